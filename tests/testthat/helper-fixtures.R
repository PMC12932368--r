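# Shared fixtures, built once per test run and cached.

.fixtures <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (!exists(name, envir = .fixtures)) {
    assign(name, force(expr), envir = .fixtures)
  }
  get(name, envir = .fixtures)
}

tiny_params <- function(...) {
  args <- utils::modifyList(
    list(n_chromosomes = 2, n_qtn_per_chr = 20, n_snp_per_chr = 20,
         n_founders = 20, effective_pop_size = 30,
         burnin_generations = 60, sites_per_chr = 300),
    list(...))
  do.call(genome_params, args)
}

tiny_pop <- function() {
  cached("tiny_pop", {
    gp <- tiny_params()
    assign_loci(simulate_founder_haplotypes(gp, seed = 42), gp, seed = 42)
  })
}

tiny_trait <- function(mu_delta = 0.5) {
  cached(paste0("tiny_trait_", mu_delta),
         sample_trait(tiny_pop(), mu_delta, 0.2, 20, seed = 7))
}

# homozygous line population built directly from an allele matrix (lines in
# rows), on a single chromosome with 1-cM spacing; roles default to QTN
make_line_pop <- function(B, role = "QTN", pool = "female", cycle = 1L) {
  n <- nrow(B); l <- ncol(B)
  sparsecross:::new_line_pop(
    haps = list(t(B)), pos = list(seq_len(l)),
    role = list(rep(role, l)), ids = sprintf("L%03d", seq_len(n)),
    family = rep("fam1", n), pool = pool, cycle = cycle,
    mother = rep("p1", n), father = rep("p2", n), chr_len_cM = l + 1)
}

# matching trait architecture for a make_line_pop population
make_trait <- function(a, d, mu_delta = 0) {
  structure(list(chr = rep(1L, length(a)), row = seq_along(a),
                 pos = seq_along(a), a = a,
                 delta = ifelse(a == 0, 0, d / abs(a)), d = d,
                 mu_delta = mu_delta, var_delta = 0.2,
                 target_var_A = NA, scale_factor = 1,
                 scale_basis = "genic"),
            class = "trait_arch")
}

# brute-force genetic value, written independently of genetic_value()
brute_value <- function(dosage, a, d) {
  tot <- 0
  for (i in seq_along(dosage)) {
    tot <- tot + switch(dosage[i] + 1, -a[i], d[i], a[i])
  }
  tot
}

mini_config <- function(...) {
  experiment_config(scale = "mini", ...)
}
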