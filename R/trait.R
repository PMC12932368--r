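#' Extract stacked locus rows for a given role
#'
#' Internal workhorse: stacks the per-chromosome haplotype matrices restricted
#' to loci of a role into one matrix (loci in rows, haplotypes/lines in
#' columns), in chromosome order and map order within chromosomes.
#' @noRd
locus_matrix <- function(pop, role = c("QTN", "SNP", "all")) {
  role <- match.arg(role)
  rows <- lapply(seq_along(pop$haps), function(chr) {
    if (role == "all") seq_len(nrow(pop$haps[[chr]]))
    else which(pop$role[[chr]] == role)
  })
  do.call(rbind, lapply(seq_along(pop$haps), function(chr) {
    pop$haps[[chr]][rows[[chr]], , drop = FALSE]
  }))
}

#' Allele frequencies at loci of a role
#'
#' For a diploid `haplo_pop` the frequency is over all `2N` haplotypes; for a
#' homozygous `line_pop` it is over the `N` line haplotypes.
#'
#' @param pop a `haplo_pop` or `line_pop`.
#' @param role `"QTN"`, `"SNP"` or `"all"`.
#' @return numeric vector of frequencies of the 1 allele.
#' @export
allele_freq <- function(pop, role = c("QTN", "SNP", "all")) {
  rowMeans(locus_matrix(pop, match.arg(role)))
}

#' QTN allele matrix of a homozygous line population
#'
#' @param pop a `line_pop`.
#' @param role locus role to extract.
#' @return `N x L` matrix of alleles in \{0, 1\} (lines in rows).
#' @export
line_alleles <- function(pop, role = c("QTN", "SNP")) {
  t(locus_matrix(pop, match.arg(role)))
}

#' Quantitative trait architecture with directional dominance
#'
#' Samples raw additive effects `a` from a standard normal and dominance
#' degrees `delta` from `N(mu_delta, var_delta)` at the assigned QTN, then
#' rescales `a` so that the additive genetic variance in the founder
#' population equals `target_var_A`. Dominance effects are
#' `d = delta * |a|`; positive `mu_delta` gives directional dominance, and
#' loci with `delta > 1` are overdominant.
#'
#' The additive variance used for scaling is, by default, the genic variance
#' `sum(2 p q alpha^2)` with average effects `alpha = a + d (q - p)` at the
#' founder QTN frequencies (`scale_basis = "genic"`); alternatively the
#' empirical variance of founder breeding values can be used
#' (`scale_basis = "empirical"`). Because `alpha` is linear in the common
#' scale factor, the rescaling is exact.
#'
#' @param pop a `haplo_pop` with QTN assigned (see [assign_loci()]).
#' @param mu_delta mean dominance degree.
#' @param var_delta dominance-degree variance.
#' @param target_var_A additive genetic variance to scale to.
#' @param seed integer seed.
#' @param scale_basis `"genic"` or `"empirical"` (see Details).
#' @return an object of class `trait_arch` with fields `chr`, `row` (locus
#'   row within the chromosome), `pos`, `a`, `delta`, `d`, `mu_delta`,
#'   `var_delta`, `scale_factor`.
#' @export
sample_trait <- function(pop, mu_delta, var_delta = 0.2, target_var_A = 20,
                         seed = 1, scale_basis = c("genic", "empirical")) {
  scale_basis <- match.arg(scale_basis)
  stopifnot(target_var_A > 0, var_delta >= 0)
  chr_rows <- lapply(seq_along(pop$haps), function(chr) {
    which(pop$role[[chr]] == "QTN")
  })
  nq <- sum(lengths(chr_rows))
  if (nq == 0) stop("no QTN assigned; call assign_loci() first")
  set.seed(child_seed(seed, "trait"))
  a <- rnorm(nq)
  delta <- rnorm(nq, mu_delta, sqrt(var_delta))
  d <- delta * abs(a)
  q_mat <- locus_matrix(pop, "QTN")
  p <- rowMeans(q_mat)
  if (all(p == 0 | p == 1)) {
    stop("founder population is monomorphic at all QTN; cannot scale")
  }
  alpha <- a + d * (1 - 2 * p)
  va <- if (scale_basis == "genic") {
    sum(2 * p * (1 - p) * alpha^2)
  } else {
    n <- ncol(q_mat) / 2
    dos <- q_mat[, seq(1, 2 * n, by = 2), drop = FALSE] +
      q_mat[, seq(2, 2 * n, by = 2), drop = FALSE]
    var(as.vector(crossprod(dos, alpha)))
  }
  if (va <= 0) stop("additive variance is zero at the founder QTN")
  s <- sqrt(target_var_A / va)
  a <- s * a
  d <- delta * abs(a)
  structure(list(chr = rep(seq_along(chr_rows), lengths(chr_rows)),
                 row = unlist(chr_rows),
                 pos = unlist(lapply(seq_along(chr_rows), function(chr) {
                   pop$pos[[chr]][chr_rows[[chr]]]
                 })),
                 a = a, delta = delta, d = d,
                 mu_delta = mu_delta, var_delta = var_delta,
                 target_var_A = target_var_A, scale_factor = s,
                 scale_basis = scale_basis),
            class = "trait_arch")
}

#' @export
print.trait_arch <- function(x, ...) {
  cat(sprintf(
    "Trait: %d QTN, mu_delta = %g, var_delta = %g, scale factor = %.4g\n",
    length(x$a), x$mu_delta, x$var_delta, x$scale_factor))
  cat(sprintf("  overdominant loci: %.1f%%\n",
              100 * overdominance_fraction(x)))
  invisible(x)
}

#' Restrict a trait architecture to one chromosome
#' @param trait a `trait_arch`.
#' @param chr chromosome index.
#' @return a `trait_arch` containing only that chromosome's QTN.
#' @export
subset_trait <- function(trait, chr) {
  keep <- trait$chr %in% chr
  for (f in c("chr", "row", "pos", "a", "delta", "d")) {
    trait[[f]] <- trait[[f]][keep]
  }
  trait
}

#' Total genetic value of QTN genotypes
#'
#' Sums per-locus contributions `-a`, `d`, `+a` for dosages 0, 1, 2
#' (genotypes aa, Aa, AA).
#'
#' @param dosage vector of length Q, or `n x Q` matrix, of QTN dosages in
#'   \{0, 1, 2\} in trait locus order.
#' @param trait a `trait_arch`.
#' @return numeric value (or vector of values for a matrix input).
#' @export
genetic_value <- function(dosage, trait) {
  if (is.matrix(dosage)) {
    if (ncol(dosage) != length(trait$a)) stop("dosage/trait length mismatch")
    if (!all(dosage %in% c(0, 1, 2))) stop("dosage must be in {0, 1, 2}")
    as.vector(dosage %*% trait$a) - sum(trait$a) +
      as.vector((dosage == 1) %*% trait$d)
  } else {
    if (length(dosage) != length(trait$a)) stop("dosage/trait length mismatch")
    if (!all(dosage %in% c(0, 1, 2))) stop("dosage must be in {0, 1, 2}")
    sum(trait$a * (dosage - 1)) + sum(trait$d[dosage == 1])
  }
}

#' Fraction of overdominant QTN
#'
#' Proportion of QTN with dominance degree greater than one. Its expectation
#' under the sampling model is `1 - pnorm((1 - mu_delta) / sqrt(var_delta))`.
#'
#' @param trait a `trait_arch`.
#' @return proportion in \[0, 1\].
#' @export
overdominance_fraction <- function(trait) {
  mean(trait$delta > 1)
}
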