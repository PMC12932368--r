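new_line_pop <- function(haps, pos, role, ids, family, pool, cycle,
                         mother, father, chr_len_cM) {
  structure(list(haps = haps, pos = pos, role = role, ids = ids,
                 family = family, pool = pool, cycle = cycle,
                 mother = mother, father = father, chr_len_cM = chr_len_cM),
            class = "line_pop")
}

#' @export
print.line_pop <- function(x, ...) {
  cat(sprintf(
    "Line population: %d homozygous lines, %d families, pool '%s', cycle %d\n",
    length(x$ids), length(unique(x$family)), x$pool, x$cycle))
  invisible(x)
}

#' Extract one diploid genotype from a heterozygous population
#'
#' @param pop a `haplo_pop`.
#' @param i individual index.
#' @return a `diploid_geno`: per-chromosome two-column haplotype matrices
#'   plus map positions.
#' @export
get_diploid <- function(pop, i) {
  structure(list(
    haps = lapply(pop$haps, function(h) h[, c(2L * i - 1L, 2L * i),
                                          drop = FALSE]),
    pos = pop$pos, role = pop$role, chr_len_cM = pop$chr_len_cM),
    class = "diploid_geno")
}

#' Diploid genotype of a fully homozygous line
#' @param pop a `line_pop`.
#' @param i line index.
#' @return a `diploid_geno` with two identical haplotypes per chromosome.
#' @export
line_as_diploid <- function(pop, i) {
  structure(list(
    haps = lapply(pop$haps, function(h) h[, c(i, i), drop = FALSE]),
    pos = pop$pos, role = pop$role, chr_len_cM = pop$chr_len_cM),
    class = "diploid_geno")
}

#' Convert heterozygous founders into homozygous inbred lines
#'
#' Each founder contributes one randomly chosen haplotype per chromosome
#' pair, which is doubled, yielding a fully homozygous line per founder.
#'
#' @param pop a `haplo_pop`.
#' @param seed integer seed.
#' @return a `line_pop` with one line per founder.
#' @export
inbreed_founders <- function(pop, seed) {
  n <- n_ind(pop)
  set.seed(child_seed(seed, "inbreed"))
  haps <- vector("list", length(pop$haps))
  for (chr in seq_along(pop$haps)) {
    pick <- 2L * seq_len(n) - 1L + (runif(n) < 0.5)
    haps[[chr]] <- pop$haps[[chr]][, pick, drop = FALSE]
  }
  new_line_pop(haps, pop$pos, pop$role, pop$ids,
               family = pop$ids, pool = "unassigned", cycle = 0L,
               mother = pop$ids, father = pop$ids,
               chr_len_cM = pop$chr_len_cM)
}

#' Sample bi-parental crosses from a half diallel with full parent coverage
#'
#' Draws `n_crosses` distinct unordered parent pairs (no selfing) uniformly
#' at random from all `choose(n, 2)` pairs, resampling complete plans until
#' every parent appears in at least one cross.
#'
#' @param parent_ids character vector of parent labels.
#' @param n_crosses number of crosses.
#' @param seed integer seed.
#' @param max_tries resampling cap before giving up.
#' @return a `cross_plan`: data frame with columns `mother` and `father`.
#' @export
sample_half_diallel <- function(parent_ids, n_crosses, seed,
                                max_tries = 10000L) {
  n <- length(parent_ids)
  if (n < 2) stop("need at least two parents")
  n_pairs <- choose(n, 2)
  if (n_crosses > n_pairs) stop("more crosses requested than distinct pairs")
  if (n_crosses < ceiling(n / 2)) {
    stop("cannot cover every parent with so few crosses")
  }
  all_pairs <- t(utils::combn(n, 2))
  set.seed(child_seed(seed, "diallel"))
  for (try in seq_len(max_tries)) {
    pick <- all_pairs[sample.int(n_pairs, n_crosses), , drop = FALSE]
    if (length(unique(as.vector(pick))) == n) {
      plan <- data.frame(mother = parent_ids[pick[, 1]],
                         father = parent_ids[pick[, 2]],
                         stringsAsFactors = FALSE)
      class(plan) <- c("cross_plan", "data.frame")
      return(plan)
    }
  }
  stop("failed to cover all parents; infeasible cross plan")
}

#' Simulate one meiosis
#'
#' Produces a haploid gamete from a phased diploid genotype. Per chromosome,
#' the crossover count is Poisson with mean equal to the map length in
#' Morgans, crossover positions are uniform on the genetic map, there is no
#' interference, and the starting strand is random (the Haldane model).
#'
#' @param parent a `diploid_geno` (see [get_diploid()], [line_as_diploid()]).
#' @param seed integer seed.
#' @return list of per-chromosome haploid allele vectors.
#' @export
meiose <- function(parent, seed) {
  stopifnot(inherits(parent, "diploid_geno"))
  set.seed(child_seed(seed, "meiosis"))
  lapply(seq_along(parent$haps), function(chr) {
    as.vector(cpp_gametes(parent$haps[[chr]], parent$pos[[chr]],
                          parent$chr_len_cM, 1L, 2L))
  })
}

#' Derive doubled-haploid lines from a cross plan
#'
#' For each cross in `plan`, forms the F1 of the two (fully homozygous)
#' parent lines and derives `n_per_cross` doubled-haploid lines, each from an
#' independent meiosis of the F1 with the gamete doubled.
#'
#' @param parents a `line_pop` containing all parents named in `plan`.
#' @param plan a `cross_plan` from [sample_half_diallel()].
#' @param n_per_cross DH lines per cross.
#' @param seed integer seed.
#' @param cycle cycle index recorded on the new lines.
#' @param pool pool label recorded on the new lines.
#' @return a `line_pop` with `nrow(plan) * n_per_cross` homozygous lines;
#'   `family` is the cross of origin.
#' @export
dh_from_crosses <- function(parents, plan, n_per_cross, seed,
                            cycle = parents$cycle + 1L, pool = parents$pool) {
  mo <- match(plan$mother, parents$ids)
  fa <- match(plan$father, parents$ids)
  if (anyNA(mo) || anyNA(fa)) stop("cross plan names unknown parents")
  nc <- nrow(plan)
  h1 <- rep(mo, each = n_per_cross)
  h2 <- rep(fa, each = n_per_cross)
  haps <- vector("list", length(parents$haps))
  for (chr in seq_along(parents$haps)) {
    set.seed(child_seed(seed, "dh", chr))
    haps[[chr]] <- cpp_gametes(parents$haps[[chr]], parents$pos[[chr]],
                               parents$chr_len_cM, h1, h2)
  }
  fam <- rep(sprintf("%s x %s", plan$mother, plan$father), each = n_per_cross)
  ids <- sprintf("%s_C%d_L%04d", substr(pool, 1, 1), cycle,
                 seq_len(nc * n_per_cross))
  new_line_pop(haps, parents$pos, parents$role, ids, fam, pool, cycle,
               mother = rep(plan$mother, each = n_per_cross),
               father = rep(plan$father, each = n_per_cross),
               chr_len_cM = parents$chr_len_cM)
}

#' Derive doubled-haploid lines from a single F1
#'
#' @param f1 a `diploid_geno` (the phased F1).
#' @param n number of DH lines.
#' @param seed integer seed.
#' @param family family label recorded on the lines.
#' @return a `line_pop` of `n` fully homozygous lines.
#' @export
derive_dh_lines <- function(f1, n, seed, family = "F1") {
  stopifnot(inherits(f1, "diploid_geno"))
  haps <- vector("list", length(f1$haps))
  for (chr in seq_along(f1$haps)) {
    set.seed(child_seed(seed, "dh1", chr))
    haps[[chr]] <- cpp_gametes(f1$haps[[chr]], f1$pos[[chr]], f1$chr_len_cM,
                               rep(1L, n), rep(2L, n))
  }
  new_line_pop(haps, f1$pos, f1$role, sprintf("DH%04d", seq_len(n)),
               rep(family, n), pool = "unassigned", cycle = 0L,
               mother = rep(family, n), father = rep(family, n),
               chr_len_cM = f1$chr_len_cM)
}

#' Form the initial heterotic pools
#'
#' Converts the founders into homozygous lines, splits them at random into a
#' female and a male pool, and runs `generations` rounds of random crossing
#' within each pool: a half diallel of `n_crosses` bi-parental crosses among
#' the current parents, `dh_per_cross` DH lines per cross, and `n_parents`
#' lines drawn at random as the next round's parents. No trait-based
#' selection is applied; the rounds generate family structure and drift only.
#'
#' @param founders a `haplo_pop` with loci assigned.
#' @param seed integer seed.
#' @param generations rounds of random crossing (default 3).
#' @param n_crosses crosses per round per pool.
#' @param dh_per_cross DH lines per cross.
#' @param n_parents parents kept per round per pool.
#' @return list with elements `female`, `male` (the final `line_pop`s),
#'   `parents_female`, `parents_male` (the `n_parents`-line `line_pop`s
#'   drawn from them).
#' @export
form_initial_pools <- function(founders, seed, generations = 3L,
                               n_crosses = 60L, dh_per_cross = 20L,
                               n_parents = 40L) {
  lines0 <- inbreed_founders(founders, child_seed(seed, "founder_inbreed"))
  n <- n_ind(founders)
  if (n < 2 * n_parents && generations > 0) {
    stop("need at least 2 * n_parents founders")
  }
  set.seed(child_seed(seed, "pool_split"))
  idx_f <- sort(sample.int(n, floor(n / 2)))
  pools <- list(female = subset_lines(lines0, idx_f, pool = "female"),
                male = subset_lines(lines0, setdiff(seq_len(n), idx_f),
                                    pool = "male"))
  parents <- pools
  for (p in names(pools)) {
    pools[[p]]$cycle <- 0L
    parents[[p]]$cycle <- 0L
    for (g in seq_len(generations)) {
      plan <- sample_half_diallel(parents[[p]]$ids, n_crosses,
                                  child_seed(seed, "plan", p, g))
      lines <- dh_from_crosses(parents[[p]], plan, dh_per_cross,
                               child_seed(seed, "lines", p, g),
                               cycle = 0L, pool = p)
      set.seed(child_seed(seed, "pick_parents", p, g))
      parents[[p]] <- subset_lines(lines,
                                   sort(sample.int(n_ind(lines), n_parents)))
      pools[[p]] <- lines
    }
  }
  list(female = pools$female, male = pools$male,
       parents_female = parents$female, parents_male = parents$male)
}

#' Subset a line population
#' @param pop a `line_pop`.
#' @param idx line indices to keep.
#' @param pool optional new pool label.
#' @return the subset `line_pop`.
#' @export
subset_lines <- function(pop, idx, pool = pop$pool) {
  new_line_pop(lapply(pop$haps, function(h) h[, idx, drop = FALSE]),
               pop$pos, pop$role, pop$ids[idx], pop$family[idx], pool,
               pop$cycle, pop$mother[idx], pop$father[idx], pop$chr_len_cM)
}

#' Testcross genotype of two homozygous genotypes
#'
#' For inbred-by-inbred crosses the hybrid is deterministic: the dosage at
#' each locus is the sum of the two parental alleles.
#'
#' @param line,tester QTN (or marker) dosage vectors in \{0, 2\}; a dosage
#'   of 1 (heterozygous input) is an error.
#' @return hybrid dosage vector in \{0, 1, 2\}.
#' @export
make_testcross <- function(line, tester) {
  if (any(line == 1) || any(tester == 1)) {
    stop("inputs must be fully homozygous (dosages 0 or 2)")
  }
  if (length(line) != length(tester)) stop("length mismatch")
  line / 2 + tester / 2
}

#' Genetic values of testcross hybrids
#'
#' Computes the total genetic value of each (line, tester) hybrid without
#' constructing genotypes explicitly: with homozygous parents the hybrid is
#' heterozygous exactly where the parents differ.
#'
#' @param b_lines `n x Q` matrix of line QTN alleles in \{0, 1\}.
#' @param b_testers `k x Q` matrix of tester QTN alleles.
#' @param tester_of integer vector (length `n`) mapping each line to a
#'   tester row.
#' @param trait a `trait_arch`.
#' @return numeric vector of hybrid genetic values, one per line.
#' @export
testcross_values <- function(b_lines, b_testers, tester_of, trait) {
  ad <- trait$a + trait$d
  x_line <- as.vector(b_lines %*% ad)
  x_test <- as.vector(b_testers %*% ad)
  out <- numeric(nrow(b_lines))
  for (t in unique(tester_of)) {
    rows <- which(tester_of == t)
    cross <- as.vector(b_lines[rows, , drop = FALSE] %*%
                         (trait$d * b_testers[t, ]))
    out[rows] <- x_line[rows] + x_test[t] - 2 * cross - sum(trait$a)
  }
  out
}

#' Matrix of hybrid genetic values between two pools
#'
#' Exact enumeration of all pairwise hybrids between two sets of homozygous
#' lines, using per-locus linearity.
#'
#' @param b_f,b_m allele matrices (\{0, 1\}) of the two pools, lines in rows.
#' @param trait a `trait_arch`.
#' @return `nrow(b_f) x nrow(b_m)` matrix of genetic values.
#' @export
hybrid_value_matrix <- function(b_f, b_m, trait) {
  ad <- trait$a + trait$d
  x_f <- as.vector(b_f %*% ad)
  x_m <- as.vector(b_m %*% ad)
  cross <- (b_f * rep(trait$d, each = nrow(b_f))) %*% t(b_m)
  outer(x_f, x_m, "+") - 2 * cross - sum(trait$a)
}

#' Calibrate the testcross error variance from a target heritability
#'
#' Computes the genetic variance of all `n_f x n_m` possible hybrids between
#' the two parent sets by enumeration and returns
#' `sigma2_e = sigma2_G * (1 - H2) / H2`. In the breeding programs this is
#' done once, at the first cycle, with the 40 x 40 parents of the two pools,
#' and the value is then held constant across cycles.
#'
#' @param parents_f,parents_m `line_pop`s of the two pools' parents.
#' @param trait a `trait_arch`.
#' @param H2 target broad-sense heritability (0 < H2 < 1).
#' @return the error variance `sigma2_e`.
#' @export
calibrate_error_variance <- function(parents_f, parents_m, trait, H2 = 0.3) {
  stopifnot(H2 > 0, H2 < 1)
  g <- hybrid_value_matrix(line_alleles(parents_f, "QTN"),
                           line_alleles(parents_m, "QTN"), trait)
  s2g <- var(as.vector(g))
  if (s2g <= 0) stop("zero genetic variance among hybrids; cannot calibrate")
  s2g * (1 - H2) / H2
}

#' Add i.i.d. normal error to genetic values
#'
#' @param genetic_values numeric vector of hybrid genetic values.
#' @param sigma2_e error variance (>= 0).
#' @param seed integer seed.
#' @return phenotype vector.
#' @export
simulate_phenotypes <- function(genetic_values, sigma2_e, seed) {
  stopifnot(sigma2_e >= 0)
  set.seed(child_seed(seed, "pheno"))
  genetic_values + rnorm(length(genetic_values), 0, sqrt(sigma2_e))
}
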