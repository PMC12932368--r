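as_ids <- function(x) if (inherits(x, "line_pop")) x$ids else as.character(x)

#' Allocate lines to testers for a sparse testcross design
#'
#' Partitions the candidate lines uniformly at random into `k` equally sized
#' subsets, one per tester, so that every line is crossed with exactly one
#' tester and every tester carries `n / k` crosses. No family stratification
#' is applied: full-sibs may land on the same or on different testers (under
#' random allocation, related lines spread across testers in expectation).
#'
#' @param line_ids candidate line labels (or a `line_pop`).
#' @param tester_ids tester labels (or a `line_pop`); their number `k` must
#'   divide the number of lines.
#' @param seed integer seed.
#' @param design_name optional label stored on the assignment.
#' @param stratify_families if `TRUE`, lines are allocated family by family
#'   (each family spread as evenly as possible over testers) instead of by
#'   unconstrained uniform sampling; requires `line_ids` to be a `line_pop`.
#' @return a `testcross_assignment`: data frame with columns `line_id` and
#'   `tester_id`, with attributes `k` and `design_name`.
#' @export
allocate_sparse <- function(line_ids, tester_ids, seed, design_name = NULL,
                            stratify_families = FALSE) {
  fams <- if (inherits(line_ids, "line_pop")) line_ids$family else NULL
  lines <- as_ids(line_ids)
  testers <- as_ids(tester_ids)
  n <- length(lines)
  k <- length(testers)
  if (k < 1 || n < 1) stop("need at least one line and one tester")
  if (n %% k != 0) {
    stop(sprintf("number of testers (%d) must divide number of lines (%d)",
                 k, n))
  }
  set.seed(child_seed(seed, "allocate"))
  if (stratify_families) {
    if (is.null(fams)) stop("family stratification needs a line_pop input")
    assign_t <- integer(n)
    for (f in unique(fams)) {
      rows <- which(fams == f)
      reps <- ceiling(length(rows) / k)
      slots <- as.vector(replicate(reps, sample.int(k)))[seq_along(rows)]
      assign_t[rows] <- slots
    }
    # rebalance to exact equal loads
    load <- n / k
    tab <- tabulate(assign_t, k)
    while (any(tab != load)) {
      over <- which(tab > load)[1]; under <- which(tab < load)[1]
      mv <- which(assign_t == over)[1]
      assign_t[mv] <- under
      tab <- tabulate(assign_t, k)
    }
    tester_of <- assign_t
  } else {
    tester_of <- rep(seq_len(k), each = n / k)[sample.int(n)]
  }
  out <- data.frame(line_id = lines, tester_id = testers[tester_of],
                    stringsAsFactors = FALSE)
  attr(out, "k") <- k
  attr(out, "design_name") <- design_name %||% sprintf("k%d", k)
  class(out) <- c("testcross_assignment", "data.frame")
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Select testers at random from a pool
#'
#' Draws `k` distinct lines uniformly without replacement from the opposite
#' heterotic pool's current inbred lines.
#'
#' @param pool a `line_pop` (or vector of line labels).
#' @param k number of testers.
#' @param seed integer seed.
#' @return character vector of `k` tester labels.
#' @export
select_testers <- function(pool, k, seed) {
  ids <- as_ids(pool)
  if (k > length(ids)) stop("more testers requested than lines in the pool")
  set.seed(child_seed(seed, "testers"))
  ids[sample.int(length(ids), k)]
}

#' Random one-to-one pairing of two pools (incomplete factorial comparator)
#'
#' Pairs each line of one pool with exactly one line of the other pool via a
#' uniformly random bijection, producing `n` hybrids from `n + n` lines.
#' This approximates an incomplete factorial mating design in which the
#' "testers" are the unevaluated candidates of the opposite pool.
#'
#' @param pool_f,pool_m `line_pop`s (or label vectors) of equal size.
#' @param seed integer seed.
#' @return a `testcross_assignment` with `design_name`
#'   `"incomplete_factorial"`; each line of each pool appears exactly once.
#' @export
incomplete_factorial_pairs <- function(pool_f, pool_m, seed) {
  f <- as_ids(pool_f); m <- as_ids(pool_m)
  if (length(f) != length(m)) stop("pools must have equal size")
  set.seed(child_seed(seed, "factorial"))
  perm <- sample.int(length(m))
  out <- data.frame(line_id = f, tester_id = m[perm],
                    stringsAsFactors = FALSE)
  attr(out, "k") <- length(m)
  attr(out, "design_name") <- "incomplete_factorial"
  class(out) <- c("testcross_assignment", "data.frame")
  out
}
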