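#' Define a simulation scenario
#'
#' Parameters of the mixed-effects generative model for log2 expression:
#' `y_ij = mu_i + eps_ij + alpha_j`, where `alpha_j ~ N(0, eta^2)` is a
#' per-sample technical effect shared by all genes of sample j and
#' `eps_ij ~ N(0, sigma^2)` is iid noise. The alpha-free matrix
#' `x_ij = mu_i + eps_ij` is the oracle that no real pipeline observes.
#' Group B baselines are drawn as `mu_i^B ~ N(baseline_mean,
#' baseline_sd^2)`; group A means are `mu_i^B + d_i` with the effect vector
#' `d` from [make_effect_vector()].
#'
#' Default noise levels (`eta = 0.873`, `sigma = 0.617`) are estimates from
#' a large breast-cancer microarray cohort; their ratio (~1.41) means
#' per-sample technical variation dominates iid noise, which is exactly the
#' regime where normalization matters.
#'
#' @param m Number of genes.
#' @param n_A,n_B Group sample sizes.
#' @param eta Per-sample random-effect sd.
#' @param sigma iid error sd.
#' @param n_up,n_down Number of up-/down-regulated genes.
#' @param effect_floor Minimum absolute effect (log2 units) before scaling.
#' @param effect_tail_mean Mean of the exponential tail added to the floor.
#' @param effect_scale Multiplier `c` on all effects; the knob that
#'   [calibrate_effect_scale()] tunes.
#' @param baseline_mean,baseline_sd Parameters of the `mu_i^B` draw.
#' @param seed Scenario seed (fixes the effect vector; replicates add their
#'   own seeds).
#' @param name Scenario label used in benchmark tables and substreams.
#' @return An object of class `simulation_scenario`.
#' @export
simulation_scenario <- function(m, n_A = 50L, n_B = 50L,
                                eta = 0.873, sigma = 0.617,
                                n_up = 0L, n_down = 0L,
                                effect_floor = 0.5,
                                effect_tail_mean = 0.35,
                                effect_scale = 1,
                                baseline_mean = 7, baseline_sd = 1.5,
                                seed = 1L, name = "scenario") {
  m <- as.integer(m); n_up <- as.integer(n_up); n_down <- as.integer(n_down)
  if (n_up + n_down > m) stop("n_up + n_down exceeds m", call. = FALSE)
  if (eta < 0 || sigma <= 0) stop("need eta >= 0 and sigma > 0",
                                  call. = FALSE)
  if (effect_scale < 0) stop("effect_scale must be >= 0", call. = FALSE)
  if (n_A < 2L || n_B < 2L) stop("group sizes must be >= 2", call. = FALSE)
  structure(list(m = m, n_A = as.integer(n_A), n_B = as.integer(n_B),
                 eta = eta, sigma = sigma, n_up = n_up, n_down = n_down,
                 effect_floor = effect_floor,
                 effect_tail_mean = effect_tail_mean,
                 effect_scale = effect_scale,
                 baseline_mean = baseline_mean, baseline_sd = baseline_sd,
                 seed = as.integer(seed), name = name),
            class = "simulation_scenario")
}

#' Standard benchmark scenarios
#'
#' Three DE structures at n = 50 per group: `sim1` has 10,000 genes with 363
#' up- and 637 down-regulated; `sim2` halves the gene count to 5,000 (so the
#' DE proportion doubles); `sim3` keeps 5,000 genes but only the 637
#' down-regulations, the most unbalanced structure, where normalization bias
#' is strongest.
#'
#' @param name `"sim1"`, `"sim2"` or `"sim3"`.
#' @param ... Overrides passed to [simulation_scenario()].
#' @return A `simulation_scenario`.
#' @export
benchmark_scenario <- function(name = c("sim1", "sim2", "sim3"), ...) {
  name <- match.arg(name)
  defaults <- switch(name,
    sim1 = list(m = 10000L, n_up = 363L, n_down = 637L),
    sim2 = list(m = 5000L, n_up = 363L, n_down = 637L),
    sim3 = list(m = 5000L, n_up = 0L, n_down = 637L))
  args <- utils::modifyList(c(defaults, list(name = name)), list(...))
  do.call(simulation_scenario, args)
}

#' True effect vector for a scenario
#'
#' Effect magnitudes follow a shifted exponential surrogate,
#' `c * (floor + Exp(mean = tail_mean))`, mimicking the heavy-tailed shape
#' of the largest absolute log2 fold changes in real data: a hard floor
#' keeps every true effect detectable in principle, the exponential tail
#' supplies occasional large effects. The first `n_up` genes get positive
#' effects, the next `n_down` negative ones, the rest zero (gene positions
#' carry no meaning for any method compared here). Reproducible from the
#' scenario seed.
#'
#' @param scenario A [simulation_scenario()].
#' @return Numeric vector `d` of length `m`.
#' @export
make_effect_vector <- function(scenario) {
  stopifnot(inherits(scenario, "simulation_scenario"))
  n_de <- scenario$n_up + scenario$n_down
  d <- numeric(scenario$m)
  if (n_de > 0L) {
    mag <- with_seed(substream_seed(scenario$seed, "effects"),
                     scenario$effect_floor +
                       stats::rexp(n_de, rate = 1 / scenario$effect_tail_mean))
    mag <- scenario$effect_scale * mag
    signs <- rep(c(1, -1), c(scenario$n_up, scenario$n_down))
    d[seq_len(n_de)] <- signs * mag
  }
  d
}

#' Simulate one replicate dataset
#'
#' Draws `mu^B`, iid noise and per-sample effects afresh for the replicate
#' (the effect vector `d` is a property of the scenario and stays fixed
#' across replicates). Returns both the observed matrix `y` and the oracle
#' matrix `x`; their difference is constant down each column (the column's
#' alpha), exactly.
#'
#' @param scenario A [simulation_scenario()].
#' @param replicate_seed Integer seed for this replicate's random draws.
#' @return An object of class `simulated_data`: list with `y`, `x`
#'   (expression matrices), `design` ([group_design()]), `truth`
#'   (factor: up/down/null per gene), and `d`.
#' @export
simulate_dataset <- function(scenario, replicate_seed = scenario$seed) {
  stopifnot(inherits(scenario, "simulation_scenario"))
  m <- scenario$m; n_A <- scenario$n_A; n_B <- scenario$n_B
  d <- make_effect_vector(scenario)
  mu_B <- with_seed(substream_seed(replicate_seed, "mu"),
                    stats::rnorm(m, scenario$baseline_mean,
                                 scenario$baseline_sd))
  mu <- cbind(matrix(mu_B + d, m, n_A), matrix(mu_B, m, n_B))
  eps <- with_seed(substream_seed(replicate_seed, "eps"),
                   matrix(stats::rnorm(m * (n_A + n_B), 0, scenario$sigma),
                          m, n_A + n_B))
  alpha <- with_seed(substream_seed(replicate_seed, "alpha"),
                     stats::rnorm(n_A + n_B, 0, scenario$eta))
  gene_ids <- sprintf("g%0*d", nchar(m), seq_len(m))
  sample_ids <- sprintf("s%0*d", nchar(n_A + n_B), seq_len(n_A + n_B))
  x <- mu + eps
  y <- sweep(x, 2L, alpha, "+")
  dimnames(x) <- dimnames(y) <- list(gene_ids, sample_ids)
  design <- group_design(stats::setNames(rep(c("A", "B"), c(n_A, n_B)),
                                         sample_ids))
  truth <- factor(ifelse(d > 0, "up", ifelse(d < 0, "down", "null")),
                  levels = c("up", "down", "null"))
  structure(list(y = y, x = x, design = design, truth = truth, d = d,
                 scenario = scenario),
            class = "simulated_data")
}

#' Power and type I error of a set of DE calls
#'
#' @param is_de Logical vector of calls.
#' @param truth Per-gene truth labels (`"up"`, `"down"`, `"null"`).
#' @return List with `power` and `type1`, both in percent. Power is `NA`
#'   when there are no truly DE genes.
#' @export
evaluate_calls <- function(is_de, truth) {
  if (length(is_de) != length(truth)) {
    stop("is_de and truth lengths differ", call. = FALSE)
  }
  is_de <- as.logical(is_de)
  is_de[is.na(is_de)] <- FALSE
  de <- truth != "null"
  power <- if (any(de)) 100 * sum(is_de & de) / sum(de) else NA_real_
  type1 <- if (any(!de)) 100 * sum(is_de & !de) / sum(!de) else NA_real_
  list(power = power, type1 = type1)
}

#' Calibrate the effect scale against a target oracle power
#'
#' Real studies define effect sizes implicitly through the data; a
#' simulation needs an explicit knob. This routine bisects the effect-scale
#' multiplier `c` until the oracle test (pooled t on the alpha-free matrix,
#' BH at `alpha`) reaches a target mean power, making scenarios from
#' different sources comparable on the oracle scale. Each evaluation reuses
#' the same replicate seeds (common random numbers), so the power curve seen
#' by the bisection is monotone in `c` up to floating point.
#'
#' @param scenario A [simulation_scenario()].
#' @param target_oracle_power Target mean oracle power, percent, in (5, 99.5).
#' @param tol Stop when the achieved power is within `tol` percentage points.
#' @param reps_per_eval Replicates averaged per power evaluation.
#' @param alpha BH threshold used for the power definition.
#' @param bracket Search interval for `c`.
#' @param max_iter Bisection iteration cap.
#' @return List with `effect_scale` and `achieved_power`.
#' @export
calibrate_effect_scale <- function(scenario, target_oracle_power,
                                   tol = 0.3, reps_per_eval = 10L,
                                   alpha = 0.05,
                                   bracket = c(0.05, 5), max_iter = 60L) {
  stopifnot(inherits(scenario, "simulation_scenario"))
  if (target_oracle_power <= 5 || target_oracle_power >= 99.5) {
    stop("target_oracle_power must be in (5, 99.5)", call. = FALSE)
  }
  rep_seeds <- vapply(seq_len(reps_per_eval), function(r)
    substream_seed(scenario$seed, "calibration", r), integer(1L))
  eval_power <- function(scale) {
    sc <- scenario
    sc$effect_scale <- scale
    mean(vapply(rep_seeds, function(rs) {
      sim <- simulate_dataset(sc, rs)
      res <- oracle_test(sim$x, sim$design)
      calls <- bh_adjust(res$p_raw) < alpha
      evaluate_calls(calls, sim$truth)$power
    }, numeric(1L)))
  }
  lo <- bracket[1L]; hi <- bracket[2L]
  p_lo <- eval_power(lo); p_hi <- eval_power(hi)
  if (target_oracle_power < p_lo || target_oracle_power > p_hi) {
    stop(sprintf(paste0("target power %.2f%% not bracketed: power is ",
                        "%.2f%% at scale %.3g and %.2f%% at scale %.3g"),
                 target_oracle_power, p_lo, lo, p_hi, hi), call. = FALSE)
  }
  for (it in seq_len(max_iter)) {
    mid <- (lo + hi) / 2
    p_mid <- eval_power(mid)
    if (abs(p_mid - target_oracle_power) <= tol) {
      return(list(effect_scale = mid, achieved_power = p_mid))
    }
    if (p_mid < target_oracle_power) lo <- mid else hi <- mid
  }
  stop(sprintf("calibration did not converge within %d iterations (last %.2f%%)",
               max_iter, p_mid), call. = FALSE)
}

#' Run the power / type-I-error benchmark
#'
#' For each scenario and replicate, simulates one dataset and evaluates
#' every requested method on it: `oracle` sees the alpha-free matrix;
#' `global`, `mediqr`, `quantile`, `loess` run normalize -> per-gene t-test
#' -> BH on the observed matrix; `sd_mean`, `sd_median`, `sd_mftm` run
#' super-delta with the corresponding summarizer. All methods within a
#' replicate see identical data. Calls use BH-adjusted p < `alpha`
#' (`call_rule = "adjp"`, default) or additionally the fold-change gate
#' (`"adjp_fc"`).
#'
#' @param scenarios A `simulation_scenario` or list of them.
#' @param methods Character subset of `c("oracle", "global", "mediqr",
#'   "quantile", "loess", "sd_mean", "sd_median", "sd_mftm")`.
#' @param replicates Replicates per scenario.
#' @param seed Master seed; replicate substreams derive from it.
#' @param call_rule `"adjp"` or `"adjp_fc"`.
#' @param alpha BH threshold.
#' @param fc_threshold Fold-change threshold for `"adjp_fc"`.
#' @param classic_test t-test variant for the four classical methods
#'   (`"welch"` default).
#' @param n_baseline Baseline panel size for super-delta (capped at m - 1).
#' @param trim_proportion MFTM trim fraction.
#' @param loess_mode Cyclic loess mode for the `loess` method (`"fast"`
#'   default, which is what makes repeated benchmark runs tractable).
#' @return A `benchmark_table`: data.frame with columns scenario, method,
#'   metric (`power` / `type1`), mean, sd, replicates (values in percent).
#'   Per-replicate values are attached as attribute `"replicate_values"`.
#' @export
run_benchmark <- function(scenarios,
                          methods = c("oracle", "global", "mediqr",
                                      "quantile", "loess", "sd_mean",
                                      "sd_median", "sd_mftm"),
                          replicates = 20L, seed = 1L,
                          call_rule = c("adjp", "adjp_fc"),
                          alpha = 0.05, fc_threshold = 1.25,
                          classic_test = c("welch", "pooled"),
                          n_baseline = 1000L, trim_proportion = 0.20,
                          loess_mode = "fast") {
  if (inherits(scenarios, "simulation_scenario")) {
    scenarios <- list(scenarios)
  }
  all_methods <- c("oracle", "global", "mediqr", "quantile", "loess",
                   "sd_mean", "sd_median", "sd_mftm")
  methods <- match.arg(methods, all_methods, several.ok = TRUE)
  call_rule <- match.arg(call_rule)
  classic_test <- match.arg(classic_test)
  use_fc <- call_rule == "adjp_fc"

  rows <- list()
  rep_store <- list()
  for (sc in scenarios) {
    stopifnot(inherits(sc, "simulation_scenario"))
    k_base <- if (!identical(n_baseline, "all") && n_baseline >= sc$m)
      "all" else n_baseline
    vals <- array(NA_real_, dim = c(replicates, length(methods), 2L),
                  dimnames = list(NULL, methods, c("power", "type1")))
    for (r in seq_len(replicates)) {
      rep_seed <- substream_seed(seed, sc$name, r)
      sim <- simulate_dataset(sc, rep_seed)
      idx <- design_indices(sim$design, sim$y)
      for (mth in methods) {
        if (mth == "oracle") {
          res <- oracle_test(sim$x, sim$design)
          p_adj <- bh_adjust(res$p_raw)
          fc <- rowMeans(sim$x[, idx$A, drop = FALSE]) -
            rowMeans(sim$x[, idx$B, drop = FALSE])
        } else if (mth %in% c("global", "mediqr", "quantile", "loess")) {
          xn <- if (mth == "loess")
            normalize_cyclic_loess(sim$y, mode = loess_mode)
          else normalize_matrix(sim$y, method = mth)
          res <- two_sample_t(xn, sim$design, variant = classic_test)
          p_adj <- bh_adjust(res$p_raw)
          fc <- rowMeans(xn[, idx$A, drop = FALSE]) -
            rowMeans(xn[, idx$B, drop = FALSE])
        } else {
          summ <- sub("^sd_", "", mth)
          cfg <- superdelta_config(summarizer = summ,
                                   trim_proportion = trim_proportion,
                                   n_baseline = k_base,
                                   df_rule = "pooled",
                                   seed = substream_seed(rep_seed, mth))
          sdres <- superdelta_test(sim$y, sim$design, cfg)
          p_adj <- sdres$table$p_adj
          fc <- sdres$table$effect_log2
        }
        calls <- if (use_fc)
          select_degs(p_adj, fc, alpha = alpha, fc_threshold = fc_threshold)
        else !is.na(p_adj) & p_adj < alpha
        ev <- evaluate_calls(calls, sim$truth)
        vals[r, mth, "power"] <- ev$power
        vals[r, mth, "type1"] <- ev$type1
      }
    }
    for (mth in methods) {
      for (metric in c("power", "type1")) {
        v <- vals[, mth, metric]
        rows[[length(rows) + 1L]] <- data.frame(
          scenario = sc$name, method = mth, metric = metric,
          mean = mean(v), sd = stats::sd(v), replicates = replicates,
          stringsAsFactors = FALSE)
      }
    }
    rep_store[[sc$name]] <- vals
  }
  out <- do.call(rbind, rows)
  attr(out, "replicate_values") <- rep_store
  class(out) <- c("benchmark_table", "data.frame")
  out
}
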