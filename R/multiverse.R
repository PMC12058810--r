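#' Enumerate analysis universes
#'
#' Full Cartesian product of the catalog's four decision points —
#' cleaning configuration, trial filter, outlier rule, model family — in
#' deterministic nested order (cleaning, filter, outlier, model), with
#' redundant no-trimming duplicates collapsed: `scope = "none"` appears
#' with exactly one placeholder regardless of how many `k_sd` levels the
#' catalog lists (a no-trimming decision combined with a cutoff is
#' illogical).
#'
#' @param catalog list with elements `cleaning` (named list of
#'   [cleaning_config()]s), `min_fixations` (integer vector),
#'   `outliers` (list of [outlier_rule()]s), `models` (character vector of
#'   model families).
#' @return a `data.table` of class `universe_specs`, one row per universe
#'   (`universe_id`, `cleaning_id`, `min_fixations`, `outlier_scope`,
#'   `outlier_k`, `model`), with the cleaning configs attached as the
#'   `cleaning_configs` attribute.
#' @export
enumerate_universes <- function(catalog) {
  for (dim in c("cleaning", "min_fixations", "outliers", "models"))
    if (!length(catalog[[dim]]))
      stop("catalog dimension '", dim, "' is empty")
  ol <- data.table(
    outlier_scope = vapply(catalog$outliers, `[[`, "", "scope"),
    outlier_k = vapply(catalog$outliers, function(r) as.numeric(r$k_sd), 0))
  ol <- unique(ol)  # collapses duplicate none-scope placeholders
  cl_ids <- names(catalog$cleaning)
  grid <- CJ(model = catalog$models, oi = seq_len(nrow(ol)),
             min_fixations = as.integer(catalog$min_fixations),
             cleaning_id = cl_ids, sorted = FALSE)
  ## CJ varies the last column fastest; reorder so cleaning is outermost
  specs <- data.table(cleaning_id = grid$cleaning_id,
                      min_fixations = grid$min_fixations,
                      outlier_scope = ol$outlier_scope[grid$oi],
                      outlier_k = ol$outlier_k[grid$oi],
                      model = grid$model)
  setorder(specs, cleaning_id, min_fixations, outlier_scope, outlier_k,
            model)
  ## restore catalog order for cleaning ids (setorder sorts lexically)
  specs[, cleaning_id := factor(cleaning_id, levels = cl_ids)]
  setorder(specs, cleaning_id)
  specs[, cleaning_id := as.character(cleaning_id)]
  specs[, universe_id := sprintf("%s|f%d|%s%s|%s", cleaning_id, min_fixations,
                                 outlier_scope,
                                 ifelse(is.na(outlier_k), "",
                                        paste0("_k", outlier_k)), model)]
  setcolorder(specs, c("universe_id", "cleaning_id", "min_fixations",
                       "outlier_scope", "outlier_k", "model"))
  structure(specs, class = c("universe_specs", class(specs)),
            cleaning_configs = catalog$cleaning)
}

#' The standard universe catalog
#'
#' The 14-configuration cleaning catalog crossed with trial filters
#' `> 0 / > 3 / > 5`, seven outlier rules (none, and grand / subject /
#' subject-by-condition scopes at 2.5 and 3 SD), and the three model
#' families: 14 x 3 x 7 x 3 = 882 universes.
#'
#' @return a catalog list suitable for [enumerate_universes()].
#' @export
standard_catalog <- function() {
  list(cleaning = cleaning_catalog(),
       min_fixations = c(0L, 3L, 5L),
       outliers = c(list(outlier_rule("none")),
                    unlist(lapply(c("grand", "subject", "subject_condition"),
                                  function(s) lapply(c(2.5, 3),
                                                     function(k) outlier_rule(s, k))),
                           recursive = FALSE)),
       models = c("lmm_identity", "lmm_log", "glmm_gamma"))
}

## the data pipeline shared by every universe: cleaning -> trial filter ->
## SFD extraction -> outlier trimming, in this fixed order
pipeline_observations <- function(ts, cleaning_cfg, min_fixations, rule) {
  cleaned <- apply_cleaning(ts, cleaning_cfg)
  filtered <- filter_trials(cleaned$trialset, min_fixations)
  obs <- extract_sfd(filtered)
  remove_outliers(obs, rule)
}

#' Run a single universe
#'
#' Applies the fixed pipeline order — cleaning, trial filter, single
#' fixation duration extraction, outlier removal, model fit — and records
#' the number of observations removed relative to the no-cleaning
#' baseline.  Model-level errors are captured as non-converged results,
#' never raised.
#'
#' @param ts a [trialset()].
#' @param spec one row of a [enumerate_universes()] table (as a list or
#'   single-row `data.table`).
#' @param cleaning_configs named list of [cleaning_config()]s.
#' @param baseline list with `n_obs` and `fingerprint` of the no-cleaning
#'   baseline observation table (`NULL` to skip the comparison).
#' @param alpha significance level passed to the model.
#' @return an object of class `universe_result`.
#' @export
run_universe <- function(ts, spec, cleaning_configs,
                         baseline = NULL, alpha = 0.05) {
  spec <- as.list(spec)
  rule <- if (spec$outlier_scope == "none") outlier_rule("none")
  else outlier_rule(spec$outlier_scope, spec$outlier_k)
  obs <- pipeline_observations(ts, cleaning_configs[[spec$cleaning_id]],
                               spec$min_fixations, rule)
  fp <- fingerprint_observations(obs)
  mr <- tryCatch(fit_model(obs, model_spec(spec$model, alpha)),
                 error = function(e) {
                   structure(list(family = spec$model, beta_freq = NA_real_,
                                  se_beta = NA_real_, stat = NA_real_,
                                  p_value = NA_real_, significant = FALSE,
                                  converged = FALSE, n_obs = nrow(obs),
                                  intercept = NA_real_, effect_ms = NA_real_,
                                  alpha = alpha,
                                  messages = conditionMessage(e)),
                             class = "model_result")
                 })
  structure(list(spec = spec, model_result = mr, n_obs = nrow(obs),
                 n_obs_removed_vs_baseline =
                   if (is.null(baseline)) NA_integer_
                 else baseline$n_obs - nrow(obs),
                 dataset_fingerprint = fp),
            class = "universe_result")
}

#' Run a full multiverse
#'
#' Executes every universe over the trial set.  The label-independent
#' pipeline stages are shared across universes that agree on them
#' (cleaning per configuration, filtering/extraction per configuration and
#' filter level, trimming per outlier rule), so each distinct observation
#' table is built once; the result is identical to running
#' [run_universe()] per spec.  Model fits may be parallelized; the
#' partition is deterministic and results are reassembled in spec order,
#' so the output does not depend on the degree of parallelism.
#'
#' @param ts a [trialset()].
#' @param specs a [enumerate_universes()] table.
#' @param parallelism number of worker processes for model fitting
#'   (forked; falls back to serial where unsupported).
#' @param alpha significance level.
#' @return an object of class `multiverse_result`: `universes` (list of
#'   `universe_result` in spec order), `table` (summary `data.table`),
#'   `n_significant`, `n_nonconverged`, `dashboard` (binary matrix,
#'   decision levels x universes in curve order), `baseline`.
#' @export
run_multiverse <- function(ts, specs, parallelism = 1L, alpha = 0.05) {
  stopifnot(nrow(specs) >= 1)
  cfgs <- attr(specs, "cleaning_configs")
  if (is.null(cfgs)) stop("specs carry no cleaning_configs attribute")

  baseline_cfg <- cleaning_config("baseline_no_cleaning",
                                  stage1 = list(enabled = FALSE),
                                  stage2 = list(enabled = FALSE),
                                  stage3 = list(enabled = FALSE),
                                  stage4 = list(enabled = FALSE))
  base_obs <- pipeline_observations(ts, baseline_cfg, 0L, outlier_rule("none"))
  baseline <- list(n_obs = nrow(base_obs),
                   fingerprint = fingerprint_observations(base_obs))

  ## stage caches keyed on the decisions that produce each intermediate
  sp <- as.data.table(specs)
  obs_cache <- new.env(parent = emptyenv())
  get_obs <- function(cleaning_id, min_fix, scope, k) {
    ckey <- paste0("c:", cleaning_id)
    if (is.null(obs_cache[[ckey]]))
      obs_cache[[ckey]] <- apply_cleaning(ts, cfgs[[cleaning_id]])$trialset
    fkey <- paste0(ckey, "|f:", min_fix)
    if (is.null(obs_cache[[fkey]]))
      obs_cache[[fkey]] <- extract_sfd(filter_trials(obs_cache[[ckey]], min_fix))
    okey <- paste0(fkey, "|o:", scope, ":", k)
    if (is.null(obs_cache[[okey]])) {
      rule <- if (scope == "none") outlier_rule("none") else outlier_rule(scope, k)
      o <- remove_outliers(obs_cache[[fkey]], rule)
      obs_cache[[okey]] <- list(obs = o, fp = fingerprint_observations(o))
    }
    obs_cache[[okey]]
  }

  jobs <- vector("list", nrow(sp))
  for (i in seq_len(nrow(sp))) {
    jobs[[i]] <- get_obs(sp$cleaning_id[i], sp$min_fixations[i],
                         sp$outlier_scope[i], sp$outlier_k[i])
  }

  fit_one <- function(i) {
    obs <- jobs[[i]]$obs
    tryCatch(fit_model(obs, model_spec(sp$model[i], alpha)),
             error = function(e) {
               structure(list(family = sp$model[i], beta_freq = NA_real_,
                              se_beta = NA_real_, stat = NA_real_,
                              p_value = NA_real_, significant = FALSE,
                              converged = FALSE, n_obs = nrow(obs),
                              intercept = NA_real_, effect_ms = NA_real_,
                              alpha = alpha, messages = conditionMessage(e)),
                         class = "model_result")
             })
  }
  idx <- seq_len(nrow(sp))
  fits <- if (parallelism > 1L && .Platform$OS.type == "unix") {
    parallel::mclapply(idx, fit_one, mc.cores = parallelism,
                       mc.preschedule = TRUE)
  } else lapply(idx, fit_one)

  universes <- lapply(idx, function(i) {
    structure(list(spec = as.list(sp[i]),
                   model_result = fits[[i]], n_obs = nrow(jobs[[i]]$obs),
                   n_obs_removed_vs_baseline = baseline$n_obs - nrow(jobs[[i]]$obs),
                   dataset_fingerprint = jobs[[i]]$fp),
              class = "universe_result")
  })

  tab <- data.table(
    universe_id = sp$universe_id, cleaning_id = sp$cleaning_id,
    min_fixations = sp$min_fixations, outlier_scope = sp$outlier_scope,
    outlier_k = sp$outlier_k, model = sp$model,
    beta_freq = vapply(fits, function(f) f$beta_freq, 0),
    se_beta = vapply(fits, function(f) f$se_beta, 0),
    p_value = vapply(fits, function(f) f$p_value, 0),
    significant = vapply(fits, function(f) isTRUE(f$significant), TRUE),
    converged = vapply(fits, function(f) isTRUE(f$converged), TRUE),
    effect_ms = vapply(fits, function(f) f$effect_ms, 0),
    n_obs = vapply(universes, function(u) u$n_obs, 0),
    n_obs_removed = vapply(universes, function(u)
      as.numeric(u$n_obs_removed_vs_baseline), 0),
    fingerprint = vapply(universes, function(u) u$dataset_fingerprint, ""))

  res <- structure(list(
    universes = universes, table = tab,
    n_significant = sum(tab$significant),
    n_nonconverged = sum(!tab$converged),
    baseline = baseline, alpha = alpha), class = "multiverse_result")
  res$dashboard <- dashboard_table(res)
  res
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.multiverse_result <- function(x, ...) {
  cat(sprintf("<multiverse_result> %d universes: %d significant, %d non-converged\n",
              nrow(x$table), x$n_significant, x$n_nonconverged))
  invisible(x)
}

#' Shuffle frequency labels at the item level
#'
#' Permutes the item-to-condition map uniformly at random (labels move as
#' a block, preserving the condition balance); every fixation row inherits
#' its item's new label.  Uses the caller's RNG state.  Shuffled data fed
#' through the full pipeline carry no frequency/duration association, the
#' device behind the permutation null.
#'
#' @param ts a [trialset()].
#' @return the relabeled trial set.
#' @export
permute_labels <- function(ts) {
  items <- copy(as.data.table(ts$items))
  perm <- sample.int(nrow(items))
  items[, condition := condition[perm]]
  fx <- copy(ts$fixations)
  fx[, condition := items$condition[match(item_id, items$item_id)]]
  trialset(fx, items, ts$geometry, ia = ts$ia, validate = FALSE)
}

#' Paper-style permutation p-value bound
#'
#' The bound quoted when no shuffled multiverse reaches the empirical
#' significant-universe count: the multiverse is rarer than one in
#' `n_perm` shuffles, i.e. `p < 1/n_perm`.
#'
#' @param n_perm number of permutations.
#' @return `1 / n_perm`.
#' @export
perm_p_bound <- function(n_perm) {
  stopifnot(n_perm >= 1)
  1 / n_perm
}

#' Permutation test for multiverse-level significance
#'
#' Reruns the complete multiverse on `n_perm` label-shuffled copies of the
#' raw trial set and compares the empirical count of significant universes
#' with the null counts.  Reports the add-one permutation p-value
#' `(1 + #[null >= empirical]) / (1 + n_perm)` and, separately, the
#' paper-style bound `p < 1/n_perm` (flagged as applicable when no null
#' count reaches the empirical count).
#'
#' @param ts a [trialset()].
#' @param specs a [enumerate_universes()] table.
#' @param n_perm number of permutations (>= 1).
#' @param seed integer seed governing the label shuffles.
#' @param parallelism forwarded to [run_multiverse()].
#' @param alpha significance level.
#' @return an object of class `permutation_result`: `empirical_count`,
#'   `null_counts`, `p_value`, `p_bound`, `bound_applies`, `n_perm`.
#' @export
permutation_test <- function(ts, specs, n_perm, seed = 1L,
                             parallelism = 1L, alpha = 0.05) {
  if (n_perm < 1) stop("n_perm must be at least 1")
  emp <- run_multiverse(ts, specs, parallelism = parallelism, alpha = alpha)
  null_counts <- integer(n_perm)
  for (b in seq_len(n_perm)) {
    null_counts[b] <- with_subseed(seed, 100000L + b, {
      shuffled <- permute_labels(ts)
      run_multiverse(shuffled, specs, parallelism = parallelism,
                     alpha = alpha)$n_significant
    })
  }
  exceed <- sum(null_counts >= emp$n_significant)
  structure(list(empirical_count = emp$n_significant,
                 null_counts = null_counts,
                 p_value = (1 + exceed) / (1 + n_perm),
                 p_bound = perm_p_bound(n_perm),
                 bound_applies = exceed == 0L,
                 n_perm = n_perm,
                 empirical = emp), class = "permutation_result")
}

#' @export
print.permutation_result <- function(x, ...) {
  cat(sprintf("<permutation_result> empirical = %d significant; add-one p = %.4g%s\n",
              x$empirical_count, x$p_value,
              if (x$bound_applies)
                sprintf(" (paper-style bound: p < %.4g)", x$p_bound) else ""))
  invisible(x)
}
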