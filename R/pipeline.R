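#' Experiment configuration
#'
#' Bundles all settings of a simulation experiment: the dominance scenario,
#' the testcross designs to compare, cycle and replicate counts, and the
#' problem-size profile. Three profiles are shipped:
#'
#' * `"paper"` — the full-scale program: 80 founders, 10 chromosomes with
#'   500 QTN + 500 SNP each, two pools of 40 parents, 60 crosses x 20 DH
#'   = 1,200 lines per pool per cycle.
#' * `"desk"` — a reduced profile for interactive work: 80 founders,
#'   100 QTN + 100 SNP per chromosome, 40 parents, 40 crosses x 10 DH
#'   = 400 lines per pool.
#' * `"mini"` — the smallest profile that preserves the program structure:
#'   40 founders, 50 QTN + 50 SNP per chromosome, 20 parents, 20 crosses
#'   x 10 DH = 200 lines per pool.
#'
#' @param scenario `"low"`, `"medium"` or `"high"` dominance (mean dominance
#'   degrees 0.1, 0.5, 0.9), or a numeric mean dominance degree.
#' @param designs tester counts to evaluate (each must divide the number of
#'   lines), optionally including `"incomplete_factorial"`. The default
#'   takes the tester counts 1, 2, 3, 4, 5, 10, 20 that divide the
#'   profile's line count.
#' @param n_cycles breeding cycles to simulate.
#' @param eval_cycles cycles at which the accuracy protocol evaluates all
#'   designs (subset of `1:n_cycles`).
#' @param n_replicates default replicate count for experiment runners.
#' @param scale `"paper"`, `"desk"` or `"mini"`.
#' @param root_seed root seed; all randomness derives from it hierarchically.
#' @param H2 target broad-sense heritability of testcross phenotypes among
#'   the 40 x 40 parental hybrids (calibrated once, then frozen).
#' @param var_delta dominance-degree variance.
#' @param target_var_A founder additive genetic variance after scaling.
#' @param baseline_testers common testers per pool in the baseline program.
#' @param ... named overrides of profile fields (`n_parents`, `n_crosses`,
#'   `dh_per_cross`, `pool_generations`, `n_qtn_per_chr`, `n_snp_per_chr`,
#'   `n_chromosomes`, `n_founders`, `burnin_generations`, `sites_per_chr`,
#'   `n_sample_pairs`).
#' @return an `experiment_config` list.
#' @export
experiment_config <- function(scenario = "medium",
                              designs = NULL,
                              n_cycles = 15L,
                              eval_cycles = c(1, 2, 3, 5, 10, 15),
                              n_replicates = 10L,
                              scale = c("desk", "paper", "mini"),
                              root_seed = 1L,
                              H2 = 0.3,
                              var_delta = 0.2,
                              target_var_A = 20,
                              baseline_testers = 3L,
                              ...) {
  scale <- match.arg(scale)
  prof <- switch(scale,
    paper = list(n_founders = 80L, n_chromosomes = 10L,
                 n_qtn_per_chr = 500L, n_snp_per_chr = 500L,
                 n_parents = 40L, n_crosses = 60L, dh_per_cross = 20L,
                 pool_generations = 3L, n_sample_pairs = 1e5,
                 burnin_generations = 200L, sites_per_chr = 7500L),
    desk = list(n_founders = 80L, n_chromosomes = 10L,
                n_qtn_per_chr = 100L, n_snp_per_chr = 100L,
                n_parents = 40L, n_crosses = 40L, dh_per_cross = 10L,
                pool_generations = 3L, n_sample_pairs = 1e5,
                burnin_generations = 200L, sites_per_chr = 1500L),
    mini = list(n_founders = 40L, n_chromosomes = 10L,
                n_qtn_per_chr = 50L, n_snp_per_chr = 50L,
                n_parents = 20L, n_crosses = 20L, dh_per_cross = 10L,
                pool_generations = 3L, n_sample_pairs = 1e5,
                burnin_generations = 200L, sites_per_chr = 800L))
  ov <- list(...)
  unknown <- setdiff(names(ov), c(names(prof), "burnin_generations",
                                  "sites_per_chr", "chr_length_bp",
                                  "chr_length_cM", "effective_pop_size"))
  if (length(unknown)) stop("unknown overrides: ", paste(unknown, collapse = ", "))
  prof[names(ov)] <- ov
  gp_args <- prof[intersect(names(prof),
                            c("n_founders", "n_chromosomes", "n_qtn_per_chr",
                              "n_snp_per_chr", "burnin_generations",
                              "sites_per_chr", "chr_length_bp",
                              "chr_length_cM", "effective_pop_size"))]
  genome <- do.call(genome_params, gp_args)
  mu_delta <- if (is.numeric(scenario)) {
    scenario
  } else {
    switch(match.arg(scenario, c("low", "medium", "high")),
           low = 0.1, medium = 0.5, high = 0.9)
  }
  scen_label <- if (is.numeric(scenario)) sprintf("mu%g", scenario) else scenario
  n_lines <- prof$n_crosses * prof$dh_per_cross
  if (is.null(designs)) {
    k_def <- c(1, 2, 3, 4, 5, 10, 20)
    designs <- k_def[n_lines %% k_def == 0]
  }
  designs <- as.character(designs)
  for (d in designs) {
    if (d != "incomplete_factorial") {
      k <- suppressWarnings(as.integer(d))
      if (is.na(k)) stop("unknown design: ", d)
      if (n_lines %% k != 0) {
        stop(sprintf("design k=%d does not divide n_lines=%d", k, n_lines))
      }
    }
  }
  if (!all(eval_cycles %in% seq_len(max(n_cycles, 1)))) {
    if (n_cycles > 0) stop("eval_cycles must lie in 1..n_cycles")
  }
  structure(list(scenario = scen_label, mu_delta = mu_delta,
                 designs = designs, n_cycles = as.integer(n_cycles),
                 eval_cycles = as.integer(eval_cycles),
                 n_replicates = as.integer(n_replicates),
                 scale = scale, root_seed = as.integer(root_seed),
                 H2 = H2, var_delta = var_delta,
                 target_var_A = target_var_A,
                 baseline_testers = as.integer(baseline_testers),
                 n_parents = prof$n_parents, n_crosses = prof$n_crosses,
                 dh_per_cross = prof$dh_per_cross, n_lines = n_lines,
                 pool_generations = prof$pool_generations,
                 n_sample_pairs = prof$n_sample_pairs,
                 genome = genome),
            class = "experiment_config")
}

#' @export
print.experiment_config <- function(x, ...) {
  cat(sprintf("Experiment: scenario %s (mu_delta = %g), scale '%s'\n",
              x$scenario, x$mu_delta, x$scale))
  cat(sprintf("  designs: %s; %d cycles, %d lines/pool/cycle\n",
              paste(x$designs, collapse = ", "), x$n_cycles, x$n_lines))
  invisible(x)
}

#' Simulate the trait-independent foundation of one replicate
#'
#' Founder genomes, locus assignment and initial heterotic pool formation
#' involve no selection, so they are shared between dominance scenarios and
#' between testcross designs within a replicate (designs are compared from
#' identical initial pools).
#'
#' @param config an [experiment_config()].
#' @param replicate replicate index.
#' @return list with the pruned founder population, the two initial pools
#'   and their parents, and the replicate seed.
#' @export
make_foundation <- function(config, replicate) {
  seed <- child_seed(config$root_seed, "rep", replicate)
  # a chromosome's sites share one genealogy, so the segregating-site count
  # occasionally falls short for a single draw; redraw deterministically
  pop <- NULL
  for (attempt in 1:8) {
    pop <- tryCatch(
      simulate_founder_haplotypes(config$genome,
                                  child_seed(seed, "genome", attempt)),
      sparsecross_insufficient_polymorphism = function(e) NULL)
    if (!is.null(pop)) break
  }
  if (is.null(pop)) {
    stop("could not generate enough segregating sites; raise sites_per_chr")
  }
  pop <- assign_loci(pop, config$genome, child_seed(seed, "loci"))
  pop <- prune_neutral(pop)
  pools <- form_initial_pools(pop, child_seed(seed, "pools"),
                              generations = config$pool_generations,
                              n_crosses = config$n_crosses,
                              dh_per_cross = config$dh_per_cross,
                              n_parents = config$n_parents)
  list(founders = pop, pools = pools, seed = seed, replicate = replicate)
}

#' Attach a trait and error-variance calibration to a foundation
#'
#' Samples the trait for the configured dominance scenario, freezes the
#' error variance from the target heritability among the 40 x 40 parental
#' hybrids, and records the initial full-factorial hybrid mean against
#' which genetic gain is expressed.
#'
#' @param foundation from [make_foundation()].
#' @param config an [experiment_config()].
#' @return list with `trait`, `sigma2_e`, `ffm0` and QTN frequency vectors
#'   of the initial pools.
#' @export
make_trait_context <- function(foundation, config) {
  trait <- sample_trait(foundation$founders, config$mu_delta,
                        config$var_delta, config$target_var_A,
                        seed = child_seed(foundation$seed, "trait",
                                          config$scenario))
  sigma2_e <- calibrate_error_variance(foundation$pools$parents_female,
                                       foundation$pools$parents_male,
                                       trait, config$H2)
  p_f0 <- allele_freq(foundation$pools$female, "QTN")
  p_m0 <- allele_freq(foundation$pools$male, "QTN")
  list(trait = trait, sigma2_e = sigma2_e,
       ffm0 = full_factorial_mean(p_f0, p_m0, trait))
}

# generate both pools' new lines from the current parents
next_lines <- function(parents, config, seed, cycle) {
  out <- list()
  for (p in c("female", "male")) {
    plan <- sample_half_diallel(parents[[p]]$ids, config$n_crosses,
                                child_seed(seed, "plan", p, cycle))
    out[[p]] <- dh_from_crosses(parents[[p]], plan, config$dh_per_cross,
                                child_seed(seed, "dh", p, cycle),
                                cycle = cycle, pool = p)
  }
  out
}

# testcross one pool's lines against testers from the opposite pool and
# return predicted GCA scores plus the raw phenotypes, per the design
evaluate_design <- function(lines_own, lines_opp, design, context, seed) {
  trait <- context$trait
  b_own_q <- line_alleles(lines_own, "QTN")
  b_opp_q <- line_alleles(lines_opp, "QTN")
  s_own <- line_alleles(lines_own, "SNP")
  s_opp <- line_alleles(lines_opp, "SNP")
  n <- nrow(b_own_q)
  if (design == "incomplete_factorial") {
    asg <- incomplete_factorial_pairs(lines_own, lines_opp,
                                      child_seed(seed, "pairs"))
  } else {
    k <- as.integer(design)
    testers <- select_testers(lines_opp, k, child_seed(seed, "testers"))
    asg <- allocate_sparse(lines_own, testers, child_seed(seed, "alloc"))
  }
  t_idx <- match(asg$tester_id, lines_opp$ids)
  l_idx <- match(asg$line_id, lines_own$ids)
  g <- testcross_values(b_own_q[l_idx, , drop = FALSE], b_opp_q, t_idx, trait)
  phen <- simulate_phenotypes(g, context$sigma2_e, child_seed(seed, "noise"))
  if (design == "1") {
    fit <- fit_testcross_model(phen, 2 * s_own[l_idx, , drop = FALSE])
    scores <- predict_gca(2 * s_own, fit$alpha)
  } else {
    fit <- fit_pool_specific_model(phen, s_own[l_idx, , drop = FALSE],
                                   s_opp[t_idx, , drop = FALSE])
    eff <- gca_marker_effects(fit, colMeans(s_own), colMeans(s_opp))
    scores <- predict_gca(2 * s_own, eff$alpha_pool1)
  }
  # phenotype vector reordered to line order (one observation per line)
  phen_by_line <- phen[order(l_idx)]
  list(scores = scores, phen = phen_by_line, fit = fit,
       true_gca = true_gca(b_own_q, colMeans(b_opp_q), trait))
}

divergence_metrics <- function(pool_f, pool_m, trait) {
  fr <- pool_freqs(pool_f, pool_m, "QTN")
  fx <- fixed_allele_fractions(fr)
  c(nei_D = nei_min_distance(fr),
    heterosis_H = mid_parent_heterosis(fr, trait),
    frac_fixed_same = fx[["frac_same"]],
    frac_fixed_opposite = fx[["frac_opposite"]])
}

#' Run one replicate of the hybrid genetic-gain program
#'
#' Simulates the full rapid-cycle reciprocal recurrent genomic selection
#' program for a single testcross design: at each cycle both pools generate
#' their new lines (half diallel among the 40 parents, DH per cross), each
#' pool's lines are testcrossed with the design's testers drawn at random
#' from the opposite pool's current lines, phenotypes are simulated with the
#' frozen error variance, marker effects are fitted (testcross model for the
#' single-tester design, pool-specific additive + dominance model otherwise),
#' and the top lines on predicted GCA become the next parents. Genetic gain
#' is the full-factorial hybrid mean minus its value for the initial pools.
#'
#' @param config an [experiment_config()].
#' @param design a design label from `config$designs`.
#' @param replicate replicate index.
#' @param foundation optional precomputed [make_foundation()] result (so
#'   several designs and scenarios can share identical initial pools).
#' @param context optional precomputed [make_trait_context()] result.
#' @param metrics_cycles cycles at which the expensive variance components
#'   are computed (in addition to gain and divergence metrics, recorded at
#'   every cycle).
#' @return data frame of per-cycle metrics (cycle 0 = initial pools).
#' @export
run_gain_program <- function(config, design, replicate,
                             foundation = NULL, context = NULL,
                             metrics_cycles = config$eval_cycles) {
  design <- as.character(design)
  if (!design %in% config$designs) {
    stop("design not in config$designs: ", design)
  }
  if (is.null(foundation)) foundation <- make_foundation(config, replicate)
  if (is.null(context)) context <- make_trait_context(foundation, config)
  trait <- context$trait
  # the seed stream is keyed by scenario but NOT by design: designs run from
  # identical initial pools with common random numbers (same cross plans,
  # meioses and phenotype errors wherever trajectories coincide), so paired
  # design contrasts are compared under matched sampling noise
  seed <- child_seed(foundation$seed, "gain", config$scenario)
  parents <- list(female = foundation$pools$parents_female,
                  male = foundation$pools$parents_male)
  pools <- list(female = foundation$pools$female,
                male = foundation$pools$male)
  rows <- list()
  record <- function(cycle, pools, acc_f = NA_real_, acc_m = NA_real_) {
    p_f <- allele_freq(pools$female, "QTN")
    p_m <- allele_freq(pools$male, "QTN")
    dm <- divergence_metrics(pools$female, pools$male, trait)
    vc <- if (cycle %in% metrics_cycles) {
      gca_sca_variances(pools$female, pools$male, trait,
                        n_sample_pairs = config$n_sample_pairs,
                        seed = child_seed(seed, "varcomp", cycle))
    } else {
      c(var_gca_f = NA_real_, var_gca_m = NA_real_, var_sca = NA_real_,
        var_hybrid = NA_real_)
    }
    data.frame(replicate = replicate, scenario = config$scenario,
               design = design, cycle = cycle,
               gain = full_factorial_mean(p_f, p_m, trait) - context$ffm0,
               acc_genomic_f = acc_f, acc_genomic_m = acc_m,
               t(dm), t(vc), sigma2_e = context$sigma2_e,
               H2_realized = if (is.na(vc["var_hybrid"])) NA_real_ else
                 vc[["var_hybrid"]] / (vc[["var_hybrid"]] + context$sigma2_e),
               row.names = NULL)
  }
  rows[[1]] <- record(0L, pools)
  for (cycle in seq_len(config$n_cycles)) {
    lines <- next_lines(parents, config, seed, cycle)
    acc <- c(female = NA_real_, male = NA_real_)
    for (p in c("female", "male")) {
      opp <- setdiff(c("female", "male"), p)
      ev <- evaluate_design(lines[[p]], lines[[opp]], design, context,
                            child_seed(seed, "eval", p, cycle))
      acc[p] <- prediction_accuracy(ev$scores, ev$true_gca)
      parents[[p]] <- select_parents(lines[[p]], ev$scores, config$n_parents)
    }
    pools <- lines
    rows[[cycle + 1]] <- record(cycle, pools, acc[["female"]], acc[["male"]])
  }
  do.call(rbind, rows)
}

#' Run one replicate of the GCA prediction-accuracy program
#'
#' Simulates the baseline breeding program, in which every line is
#' testcrossed with the same `baseline_testers` common testers from the
#' opposite pool and parents are selected on testcross-model predictions
#' from per-line mean phenotypes. At each evaluation cycle, every configured
#' design is applied to the same set of lines with freshly drawn random
#' testers, and genomic accuracy (predicted vs true GCA) and phenotypic
#' accuracy (the design's single testcross phenotype vs true GCA) are
#' recorded per pool. Design evaluations never feed back into selection, so
#' the baseline trajectory is identical whatever designs are evaluated.
#'
#' @param config an [experiment_config()].
#' @param replicate replicate index.
#' @param foundation,context optional precomputed stages, as in
#'   [run_gain_program()].
#' @param variance_cycles cycles at which GCA/SCA variance components are
#'   computed on the baseline populations (they are the expensive part of
#'   the per-cycle metrics; pass `integer(0)` to skip them).
#' @return list with `trajectory` (per-cycle baseline metrics) and
#'   `evaluations` (per cycle x design x pool accuracy records).
#' @export
run_accuracy_program <- function(config, replicate,
                                 foundation = NULL, context = NULL,
                                 variance_cycles = config$eval_cycles) {
  if (is.null(foundation)) foundation <- make_foundation(config, replicate)
  if (is.null(context)) context <- make_trait_context(foundation, config)
  trait <- context$trait
  seed <- child_seed(foundation$seed, "accuracy", config$scenario)
  parents <- list(female = foundation$pools$parents_female,
                  male = foundation$pools$parents_male)
  traj <- list()
  evals <- list()
  for (cycle in seq_len(config$n_cycles)) {
    lines <- next_lines(parents, config, seed, cycle)
    base_acc <- c(female = NA_real_, male = NA_real_)
    for (p in c("female", "male")) {
      opp <- setdiff(c("female", "male"), p)
      b_q <- line_alleles(lines[[p]], "QTN")
      b_opp_q <- line_alleles(lines[[opp]], "QTN")
      s_own <- line_alleles(lines[[p]], "SNP")
      tg <- true_gca(b_q, colMeans(b_opp_q), trait)
      # baseline: all lines crossed with the same common testers
      testers <- select_testers(lines[[opp]], config$baseline_testers,
                                child_seed(seed, "base_testers", p, cycle))
      t_idx <- match(testers, lines[[opp]]$ids)
      n <- nrow(b_q)
      phen_mat <- vapply(t_idx, function(t) {
        g <- testcross_values(b_q, b_opp_q, rep(t, n), trait)
        simulate_phenotypes(g, context$sigma2_e,
                            child_seed(seed, "base_noise", p, cycle, t))
      }, numeric(n))
      y_mean <- rowMeans(phen_mat)
      fit <- fit_testcross_model(y_mean, 2 * s_own)
      scores <- predict_gca(2 * s_own, fit$alpha)
      base_acc[p] <- prediction_accuracy(scores, tg)
      parents[[p]] <- select_parents(lines[[p]], scores, config$n_parents)
      if (cycle %in% config$eval_cycles) {
        for (design in config$designs) {
          ev <- evaluate_design(lines[[p]], lines[[opp]], design, context,
                                child_seed(seed, "design_eval", p, cycle,
                                           design))
          evals[[length(evals) + 1]] <- data.frame(
            replicate = replicate, scenario = config$scenario,
            cycle = cycle, design = design, pool = p,
            acc_genomic = prediction_accuracy(ev$scores, ev$true_gca),
            acc_phenotypic = prediction_accuracy(ev$phen, ev$true_gca),
            row.names = NULL)
        }
      }
    }
    dm <- divergence_metrics(lines$female, lines$male, trait)
    vc <- if (cycle %in% variance_cycles) {
      gca_sca_variances(lines$female, lines$male, trait,
                        n_sample_pairs = config$n_sample_pairs,
                        seed = child_seed(seed, "varcomp", cycle))
    } else {
      c(var_gca_f = NA_real_, var_gca_m = NA_real_, var_sca = NA_real_,
        var_hybrid = NA_real_)
    }
    traj[[cycle]] <- data.frame(
      replicate = replicate, scenario = config$scenario, design = "baseline",
      cycle = cycle, acc_genomic_f = base_acc[["female"]],
      acc_genomic_m = base_acc[["male"]], t(dm), t(vc),
      sigma2_e = context$sigma2_e, row.names = NULL)
  }
  list(trajectory = do.call(rbind, traj),
       evaluations = do.call(rbind, evals))
}

#' Aggregate replicate tables into means and standard errors
#'
#' Averages every numeric metric over replicates per (scenario, design,
#' cycle) cell — pooling pools when a `pool` column is present — and adds,
#' for the `gain`, `acc_genomic` and `acc_genomic_f/m` metrics, the percent
#' difference of each design relative to the single-tester design.
#'
#' @param tables a data frame of per-replicate rows (or list of them).
#' @return data frame with columns `scenario`, `design`, `cycle`, `metric`,
#'   `mean`, `se`, `n`, and `pct_vs_k1` where applicable.
#' @export
aggregate_replicates <- function(tables) {
  if (is.list(tables) && !is.data.frame(tables)) {
    tables <- do.call(rbind, tables)
  }
  if (is.null(tables) || nrow(tables) == 0) stop("no replicate rows to aggregate")
  id_cols <- intersect(c("scenario", "design", "cycle"), names(tables))
  metrics <- setdiff(names(tables)[vapply(tables, is.numeric, logical(1))],
                     c("replicate", "cycle"))
  out <- list()
  for (mname in metrics) {
    spl <- split(tables[[mname]], tables[id_cols], drop = TRUE)
    keys <- unique(tables[id_cols])
    keys <- keys[order(do.call(paste, c(keys, sep = "\r"))), , drop = FALSE]
    key_str <- do.call(paste, c(keys, sep = "."))
    vals <- lapply(key_str, function(k) {
      v <- spl[[k]]
      v[!is.na(v)]
    })
    df <- keys
    df$metric <- mname
    df$mean <- vapply(vals, function(v) if (length(v)) mean(v) else NA_real_,
                      numeric(1))
    df$se <- vapply(vals, function(v) {
      if (length(v) > 1) sd(v) / sqrt(length(v)) else NA_real_
    }, numeric(1))
    df$n <- vapply(vals, length, numeric(1))
    out[[mname]] <- df
  }
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  if ("design" %in% names(out)) {
    pct_metrics <- intersect(unique(out$metric),
                             c("gain", "acc_genomic", "acc_genomic_f",
                               "acc_genomic_m"))
    out$pct_vs_k1 <- NA_real_
    ref <- out[out$design == "1" & out$metric %in% pct_metrics, ]
    if (nrow(ref)) {
      key <- function(d) do.call(paste, c(d[intersect(c("scenario", "cycle",
                                                        "metric"),
                                                      names(d))], sep = "."))
      ref_map <- setNames(ref$mean, key(ref))
      sel <- out$metric %in% pct_metrics
      r <- ref_map[key(out[sel, ])]
      out$pct_vs_k1[sel] <- 100 * (out$mean[sel] - r) / abs(r)
    }
  }
  out
}
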