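#' Genome simulation parameters
#'
#' Parameters of the simulated genome and of the forward-in-time burn-in used
#' to generate linkage disequilibrium in the founder population. Defaults
#' mimic a maize-like genome: 10 chromosomes of 2e8 bp / 200 cM each, a
#' per-bp mutation rate of 1.25e-8, an effective population size of 100, and
#' 500 QTN plus 500 SNP markers per chromosome.
#'
#' Only a down-sampled grid of sites is tracked per chromosome (physical
#' positions matter only through the genetic map, taken as uniform with
#' 1 cM = 1e6 bp at the defaults). `sites_per_chr` controls the grid size;
#' it must be large enough that at least `n_qtn_per_chr + n_snp_per_chr`
#' sites remain segregating among the founders after the burn-in.
#'
#' The burn-in backend is Wright-Fisher random mating at `effective_pop_size`
#' diploids for `burnin_generations` generations with Poisson-crossover
#' meiosis (no interference) and per-site mutation. Initial allele
#' frequencies are drawn from `init_spectrum`: `"neutral"` draws from the
#' standing-variation spectrum proportional to 1/(p(1-p)) truncated at
#' `init_freq_bound` (emulating variation inherited from a large ancestral
#' population, as in a domestication-bottleneck history), `"uniform"` draws
#' from U(0, 1).
#'
#' @param n_chromosomes number of chromosome pairs.
#' @param chr_length_bp physical chromosome length in base pairs.
#' @param chr_length_cM genetic chromosome length in centimorgans.
#' @param mutation_rate per-bp per-generation mutation probability.
#' @param effective_pop_size diploid population size during burn-in.
#' @param n_founders number of heterozygous founder genotypes to draw.
#' @param n_qtn_per_chr QTN per chromosome.
#' @param n_snp_per_chr SNP markers per chromosome.
#' @param burnin_generations generations of Wright-Fisher burn-in. The
#'   segregating-site frequency spectrum is quasi-stationary (near-uniform)
#'   after roughly `effective_pop_size` generations, so longer burn-ins only
#'   strengthen short-range LD while losing sites to fixation; the default
#'   of two times `effective_pop_size` generations balances the two.
#' @param sites_per_chr sites simulated per chromosome before filtering to
#'   segregating sites; default `10 * (n_qtn_per_chr + n_snp_per_chr)`.
#' @param init_spectrum `"neutral"` or `"uniform"` initial frequency spectrum.
#' @param init_freq_bound truncation of the neutral spectrum.
#' @return an object of class `genome_params`.
#' @export
genome_params <- function(n_chromosomes = 10L,
                          chr_length_bp = 2e8,
                          chr_length_cM = 200,
                          mutation_rate = 1.25e-8,
                          effective_pop_size = 100L,
                          n_founders = 80L,
                          n_qtn_per_chr = 500L,
                          n_snp_per_chr = 500L,
                          burnin_generations = 200L,
                          sites_per_chr = NULL,
                          init_spectrum = c("neutral", "uniform"),
                          init_freq_bound = 0.005) {
  init_spectrum <- match.arg(init_spectrum)
  if (is.null(sites_per_chr)) {
    sites_per_chr <- 10L * (n_qtn_per_chr + n_snp_per_chr)
  }
  p <- list(n_chromosomes = as.integer(n_chromosomes),
            chr_length_bp = chr_length_bp,
            chr_length_cM = chr_length_cM,
            mutation_rate = mutation_rate,
            effective_pop_size = as.integer(effective_pop_size),
            n_founders = as.integer(n_founders),
            n_qtn_per_chr = as.integer(n_qtn_per_chr),
            n_snp_per_chr = as.integer(n_snp_per_chr),
            burnin_generations = as.integer(burnin_generations),
            sites_per_chr = as.integer(sites_per_chr),
            init_spectrum = init_spectrum,
            init_freq_bound = init_freq_bound)
  counts <- c("n_chromosomes", "effective_pop_size", "n_founders",
              "sites_per_chr")
  for (f in counts) {
    if (p[[f]] < 1L) stop("'", f, "' must be >= 1")
  }
  if (p$n_qtn_per_chr < 0L || p$n_snp_per_chr < 0L) {
    stop("locus counts must be >= 0")
  }
  if (p$chr_length_bp < 1 || p$chr_length_cM <= 0) {
    stop("chromosome lengths must be positive")
  }
  if (p$sites_per_chr < p$n_qtn_per_chr + p$n_snp_per_chr) {
    stop("'sites_per_chr' must be at least n_qtn_per_chr + n_snp_per_chr")
  }
  # recombination rate per bp, derived, kept for reference
  p$recomb_rate_per_bp <- (p$chr_length_cM / 100) / p$chr_length_bp
  class(p) <- "genome_params"
  p
}

#' @export
print.genome_params <- function(x, ...) {
  cat("Genome parameters:\n")
  cat(sprintf("  %d chromosomes, %.3g bp / %g cM each\n",
              x$n_chromosomes, x$chr_length_bp, x$chr_length_cM))
  cat(sprintf("  Ne = %d, %d founders, burn-in %d generations (%s spectrum)\n",
              x$effective_pop_size, x$n_founders, x$burnin_generations,
              x$init_spectrum))
  cat(sprintf("  %d QTN + %d SNP per chromosome (%d sites tracked)\n",
              x$n_qtn_per_chr, x$n_snp_per_chr, x$sites_per_chr))
  invisible(x)
}

new_haplo_pop <- function(haps, pos, role, ids, chr_len_cM, params) {
  structure(list(haps = haps, pos = pos, role = role, ids = ids,
                 chr_len_cM = chr_len_cM, params = params),
            class = "haplo_pop")
}

#' @export
print.haplo_pop <- function(x, ...) {
  nl <- vapply(x$haps, nrow, integer(1))
  cat(sprintf("Haplotype population: %d individuals, %d chromosomes, %d loci\n",
              length(x$ids), length(x$haps), sum(nl)))
  invisible(x)
}

#' Number of individuals in a population
#' @param pop a `haplo_pop` or `line_pop`.
#' @return integer count.
#' @export
n_ind <- function(pop) length(pop$ids)

#' Simulate founder haplotypes with linkage disequilibrium
#'
#' Runs the Wright-Fisher burn-in independently for each chromosome, then
#' forms founder genotypes by randomly sampling chromosome pairs from the
#' burn-in population (independently per chromosome), and retains only sites
#' segregating among the founders. All loci start with role `"neutral"`;
#' see [assign_loci()].
#'
#' @param params a [genome_params()] object.
#' @param seed integer seed; the run is fully reproducible given the seed.
#' @return a `haplo_pop` with `2 * n_founders` haplotypes per chromosome.
#'   Signals a condition of class `sparsecross_insufficient_polymorphism`
#'   if any chromosome retains fewer segregating sites than
#'   `n_qtn_per_chr + n_snp_per_chr` (retry with a larger `sites_per_chr`
#'   or shorter burn-in).
#' @export
simulate_founder_haplotypes <- function(params, seed) {
  stopifnot(inherits(params, "genome_params"))
  nf <- params$n_founders
  ne <- params$effective_pop_size
  if (nf > ne) stop("n_founders cannot exceed effective_pop_size")
  haps <- vector("list", params$n_chromosomes)
  pos <- vector("list", params$n_chromosomes)
  cm_per_bp <- params$chr_length_cM / params$chr_length_bp
  for (chr in seq_len(params$n_chromosomes)) {
    set.seed(child_seed(seed, "genome", chr))
    s0 <- params$sites_per_chr
    pos_bp <- seq(1, params$chr_length_bp, length.out = s0)
    pos_cm <- pos_bp * cm_per_bp
    p0 <- switch(params$init_spectrum,
      uniform = runif(s0),
      neutral = {
        eps <- params$init_freq_bound
        u <- runif(s0, log(eps / (1 - eps)), log((1 - eps) / eps))
        1 / (1 + exp(-u))
      })
    h0 <- matrix(rbinom(s0 * 2L * ne, 1L, p0), nrow = s0)
    h <- cpp_burnin(h0, pos_cm, params$chr_length_cM,
                    params$burnin_generations, params$mutation_rate)
    idx <- sample.int(ne, nf)
    h <- h[, c(rbind(2L * idx - 1L, 2L * idx)), drop = FALSE]
    freq <- rowMeans(h)
    seg <- freq > 0 & freq < 1
    haps[[chr]] <- h[seg, , drop = FALSE]
    pos[[chr]] <- pos_cm[seg]
  }
  need <- params$n_qtn_per_chr + params$n_snp_per_chr
  n_seg <- vapply(haps, nrow, integer(1))
  if (any(n_seg < need)) {
    chr_bad <- which(n_seg < need)[1]
    stop(structure(class = c("sparsecross_insufficient_polymorphism",
                             "error", "condition"),
                   list(message = sprintf(
                     paste0("chromosome %d has only %d segregating sites ",
                            "(need %d); increase sites_per_chr or shorten ",
                            "the burn-in"), chr_bad, n_seg[chr_bad], need),
                     call = sys.call(-1))))
  }
  role <- lapply(n_seg, function(n) rep("neutral", n))
  new_haplo_pop(haps, pos, role, sprintf("F%03d", seq_len(nf)),
                params$chr_length_cM, params)
}

#' Assign QTN and SNP roles to segregating loci
#'
#' Samples `n_qtn_per_chr` QTN and `n_snp_per_chr` SNP loci per chromosome,
#' uniformly without replacement and mutually disjoint; remaining loci keep
#' role `"neutral"`.
#'
#' @param pop a `haplo_pop` from [simulate_founder_haplotypes()].
#' @param params a [genome_params()] object.
#' @param seed integer seed.
#' @return the population with its `role` vectors filled in.
#' @export
assign_loci <- function(pop, params, seed) {
  stopifnot(inherits(pop, "haplo_pop"))
  need <- params$n_qtn_per_chr + params$n_snp_per_chr
  for (chr in seq_along(pop$haps)) {
    n_loc <- nrow(pop$haps[[chr]])
    if (n_loc < need) {
      stop(sprintf("chromosome %d has %d segregating sites but %d are needed",
                   chr, n_loc, need))
    }
    set.seed(child_seed(seed, "loci", chr))
    pick <- sample.int(n_loc, need)
    role <- rep("neutral", n_loc)
    role[pick[seq_len(params$n_qtn_per_chr)]] <- "QTN"
    if (params$n_snp_per_chr > 0) {
      role[pick[params$n_qtn_per_chr + seq_len(params$n_snp_per_chr)]] <- "SNP"
    }
    pop$role[[chr]] <- role
  }
  pop
}

#' Drop neutral loci from a population
#'
#' QTN and SNP loci fully determine trait values and marker data; removing
#' neutral sites leaves the joint distribution of gametes at the retained
#' loci unchanged (crossovers are laid down on the genetic map, which is
#' preserved) while making meiosis cheaper.
#'
#' @param pop a `haplo_pop` or `line_pop` with assigned loci.
#' @return the population restricted to QTN and SNP loci.
#' @export
prune_neutral <- function(pop) {
  for (chr in seq_along(pop$haps)) {
    keep <- pop$role[[chr]] != "neutral"
    pop$haps[[chr]] <- pop$haps[[chr]][keep, , drop = FALSE]
    pop$pos[[chr]] <- pop$pos[[chr]][keep]
    pop$role[[chr]] <- pop$role[[chr]][keep]
  }
  pop
}

#' Pairwise linkage-disequilibrium summary
#'
#' Mean r-squared between locus pairs closer than `near_cM` and pairs farther
#' apart than `far_cM`, computed on haplotypes pooled over individuals, per
#' chromosome and averaged. Used as a sanity check that the burn-in generated
#' distance-dependent LD.
#'
#' @param pop a `haplo_pop`.
#' @param near_cM,far_cM distance thresholds in cM.
#' @param max_pairs cap on sampled pairs per class per chromosome.
#' @param seed seed for pair sampling.
#' @return named numeric vector with elements `r2_near` and `r2_far`.
#' @export
ld_r2_summary <- function(pop, near_cM = 1, far_cM = 50, max_pairs = 2000,
                          seed = 1) {
  set.seed(child_seed(seed, "ld"))
  near <- c(); far <- c()
  for (chr in seq_along(pop$haps)) {
    h <- pop$haps[[chr]]; p <- pop$pos[[chr]]
    n_loc <- nrow(h)
    if (n_loc < 2) next
    i <- sample.int(n_loc, min(4 * max_pairs, n_loc * 4), replace = TRUE)
    j <- sample.int(n_loc, length(i), replace = TRUE)
    d <- abs(p[i] - p[j])
    ok <- i != j
    r2 <- function(ii, jj) {
      vapply(seq_along(ii), function(k) {
        x <- h[ii[k], ]; y <- h[jj[k], ]
        if (sd(x) == 0 || sd(y) == 0) return(NA_real_)
        cor(x, y)^2
      }, numeric(1))
    }
    kn <- which(ok & d > 0 & d < near_cM)[seq_len(max_pairs)]
    kf <- which(ok & d > far_cM)[seq_len(max_pairs)]
    kn <- kn[!is.na(kn)]; kf <- kf[!is.na(kf)]
    near <- c(near, r2(i[kn], j[kn]))
    far <- c(far, r2(i[kf], j[kf]))
  }
  c(r2_near = mean(near, na.rm = TRUE), r2_far = mean(far, na.rm = TRUE))
}
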