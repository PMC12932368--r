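#' Per-QTN allele frequencies of the two heterotic pools
#'
#' @param pool_f,pool_m `line_pop`s of the female and male pool.
#' @param role locus role (`"QTN"` or `"SNP"`).
#' @return an `allele_freqs` list with `p_female`, `p_male` and
#'   `n_polymorphic` (QTN polymorphic in the pooled union).
#' @export
pool_freqs <- function(pool_f, pool_m, role = "QTN") {
  p_f <- allele_freq(pool_f, role)
  p_m <- allele_freq(pool_m, role)
  u <- (p_f + p_m) / 2
  structure(list(p_female = p_f, p_male = p_m,
                 n_polymorphic = sum(u > 0 & u < 1)),
            class = "allele_freqs")
}

freq_pair <- function(freqs, p_m = NULL) {
  if (inherits(freqs, "allele_freqs")) {
    list(f = freqs$p_female, m = freqs$p_male)
  } else {
    list(f = freqs, m = p_m)
  }
}

#' True general combining ability of homozygous lines
#'
#' The true GCA of a line is its mean hybrid genetic value over all lines of
#' the opposite pool. Because the genetic value is additive over loci and,
#' per locus, linear in the partner's allele, the mean over partners reduces
#' exactly to a per-locus marginalisation over the opposite pool's allele
#' frequencies: a line allele `b` at a locus with partner frequency `p`
#' contributes `b [p a + (1-p) d] + (1-b) [p d - (1-p) a]`.
#'
#' @param b line QTN alleles: vector (one line) or `n x Q` matrix in
#'   \{0, 1\}.
#' @param opposite_freqs QTN allele frequencies of the opposite pool.
#' @param trait a `trait_arch`.
#' @return numeric GCA value(s).
#' @export
true_gca <- function(b, opposite_freqs, trait) {
  p <- opposite_freqs
  stopifnot(length(p) == length(trait$a))
  slope <- trait$a + trait$d * (1 - 2 * p)
  const <- sum(p * trait$d - (1 - p) * trait$a)
  if (is.matrix(b)) as.vector(b %*% slope) + const else sum(b * slope) + const
}

#' Mean genetic value of the full factorial between two pools
#'
#' Exact mean over all pairwise hybrids, computed per locus from the two
#' pools' allele frequencies (linearity of the mean):
#' `sum(p_f p_m a + (p_f q_m + q_f p_m) d - q_f q_m a)`.
#'
#' @param freqs_f,freqs_m QTN allele frequencies of the two pools.
#' @param trait a `trait_arch`.
#' @return the full-factorial hybrid mean.
#' @export
full_factorial_mean <- function(freqs_f, freqs_m, trait) {
  qf <- 1 - freqs_f
  qm <- 1 - freqs_m
  sum(freqs_f * freqs_m * trait$a +
        (freqs_f * qm + qf * freqs_m) * trait$d -
        qf * qm * trait$a)
}

#' GCA, SCA and hybrid variance components of two pools
#'
#' GCA variances are the variances of true GCA over each pool's lines. The
#' hybrid variance is the variance of genetic values over all pairwise
#' hybrids (exact enumeration when the pair count is at most `max_enum`,
#' otherwise Monte Carlo over `n_sample_pairs` uniformly drawn pairs). The
#' SCA variance is the hybrid variance minus the summed GCA variances,
#' floored at zero; under pure additivity it is exactly zero in enumeration
#' mode since each hybrid value is then the sum of its parents' GCAs plus a
#' constant.
#'
#' @param pool_f,pool_m `line_pop`s.
#' @param trait a `trait_arch`.
#' @param n_sample_pairs Monte-Carlo sample size for large pools.
#' @param max_enum pair-count threshold for exact enumeration.
#' @param seed seed for the Monte-Carlo path.
#' @return named vector `var_gca_f`, `var_gca_m`, `var_sca`, `var_hybrid`.
#' @export
gca_sca_variances <- function(pool_f, pool_m, trait, n_sample_pairs = 1e5,
                              max_enum = 1e6, seed = 1) {
  b_f <- line_alleles(pool_f, "QTN")
  b_m <- line_alleles(pool_m, "QTN")
  p_f <- colMeans(b_f)
  p_m <- colMeans(b_m)
  g_f <- true_gca(b_f, p_m, trait)
  g_m <- true_gca(b_m, p_f, trait)
  pvar <- function(x) mean((x - mean(x))^2)
  n_pairs <- as.double(nrow(b_f)) * nrow(b_m)
  if (n_pairs <= max_enum) {
    vh <- pvar(as.vector(hybrid_value_matrix(b_f, b_m, trait)))
  } else {
    set.seed(child_seed(seed, "hybrid_mc"))
    i <- sample.int(nrow(b_f), n_sample_pairs, replace = TRUE)
    j <- sample.int(nrow(b_m), n_sample_pairs, replace = TRUE)
    ad <- trait$a + trait$d
    x_f <- as.vector(b_f %*% ad)
    x_m <- as.vector(b_m %*% ad)
    dm <- b_m * rep(trait$d, each = nrow(b_m))
    vals <- numeric(n_sample_pairs)
    chunk <- 2000L
    for (s in seq(1, n_sample_pairs, by = chunk)) {
      e <- min(s + chunk - 1L, n_sample_pairs)
      vals[s:e] <- x_f[i[s:e]] + x_m[j[s:e]] -
        2 * rowSums(b_f[i[s:e], , drop = FALSE] * dm[j[s:e], , drop = FALSE])
    }
    vh <- pvar(vals)
  }
  vf <- pvar(g_f)
  vm <- pvar(g_m)
  c(var_gca_f = vf, var_gca_m = vm,
    var_sca = max(0, vh - vf - vm), var_hybrid = vh)
}

#' Pearson accuracy of predicted against true GCA
#'
#' @param predicted,truth numeric vectors of equal length (>= 3).
#' @return Pearson correlation, or `NA` when either input is constant.
#' @export
prediction_accuracy <- function(predicted, truth) {
  stopifnot(length(predicted) == length(truth), length(truth) >= 3)
  if (sd(predicted) == 0 || sd(truth) == 0) return(NA_real_)
  cor(predicted, truth)
}

#' Nei's minimum genetic distance between the pools
#'
#' `D = mean((p_f - p_m)^2)` over QTN polymorphic in the pooled union of the
#' two pools (loci fixed for the same allele in both pools carry no signal
#' and are excluded; loci fixed for opposite alleles contribute 1).
#'
#' @param freqs an `allele_freqs` object (or the female frequency vector).
#' @param p_m male frequencies when `freqs` is a plain vector.
#' @return the distance, or `NA` if no QTN is polymorphic in the union.
#' @export
nei_min_distance <- function(freqs, p_m = NULL) {
  fp <- freq_pair(freqs, p_m)
  u <- (fp$f + fp$m) / 2
  poly <- u > 0 & u < 1
  if (!any(poly)) return(NA_real_)
  mean((fp$f[poly] - fp$m[poly])^2)
}

#' Mid-parent heterosis between the pools
#'
#' Falconer's expression for the deviation of the hybrid-population mean
#' from the mid-parent mean: `H = sum(d * (p_f - p_m)^2)` over QTN.
#'
#' @param freqs an `allele_freqs` object (or the female frequency vector).
#' @param trait a `trait_arch`.
#' @param p_m male frequencies when `freqs` is a plain vector.
#' @return the heterosis.
#' @export
mid_parent_heterosis <- function(freqs, trait, p_m = NULL) {
  fp <- freq_pair(freqs, p_m)
  sum(trait$d * (fp$f - fp$m)^2)
}

#' Fractions of QTN fixed for the same or for opposite alleles
#'
#' Fractions are relative to the total number of simulated QTN.
#'
#' @param freqs an `allele_freqs` object (or the female frequency vector).
#' @param p_m male frequencies when `freqs` is a plain vector.
#' @param n_total_qtn denominator; defaults to the number of QTN in `freqs`.
#' @return named vector `frac_same`, `frac_opposite`.
#' @export
fixed_allele_fractions <- function(freqs, p_m = NULL, n_total_qtn = NULL) {
  fp <- freq_pair(freqs, p_m)
  if (is.null(n_total_qtn)) n_total_qtn <- length(fp$f)
  opp <- (fp$f == 0 & fp$m == 1) | (fp$f == 1 & fp$m == 0)
  same <- (fp$f == 0 & fp$m == 0) | (fp$f == 1 & fp$m == 1)
  c(frac_same = sum(same) / n_total_qtn,
    frac_opposite = sum(opp) / n_total_qtn)
}

#' Variance fractions of the leading principal components of the GRM
#'
#' Builds a VanRaden-style genomic relationship matrix from centred marker
#' dosages and returns the fractions of total eigenvalue mass captured by
#' the first `n_components` components.
#'
#' @param genotypes `n x m` marker dosage matrix.
#' @param n_components number of leading components.
#' @return numeric vector of variance fractions, or `NA`s when the
#'   genotypes carry no variance.
#' @export
grm_pc_variance_fractions <- function(genotypes, n_components = 2) {
  stopifnot(nrow(genotypes) >= 2)
  p <- colMeans(genotypes) / 2
  denom <- 2 * sum(p * (1 - p))
  M <- sweep(genotypes, 2, 2 * p)
  if (denom <= 0 || all(M == 0)) return(rep(NA_real_, n_components))
  G <- tcrossprod(M) / denom
  ev <- pmax(eigen(G, symmetric = TRUE, only.values = TRUE)$values, 0)
  if (sum(ev) <= 0) return(rep(NA_real_, n_components))
  (ev / sum(ev))[seq_len(n_components)]
}
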