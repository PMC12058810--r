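#' Specification-curve table
#'
#' Orders universes ascending by back-transformed effect size (ties broken
#' by spec order; non-converged universes, whose effect is undefined, sort
#' last) and classifies each as `significant`, `nonsignificant`, or
#' `nonconverged`.
#'
#' @param mv a `multiverse_result`.
#' @return a `data.table`: `rank`, `universe_id`, `effect_ms`, `class`,
#'   plus the spec columns.
#' @export
specification_curve_table <- function(mv) {
  stopifnot(inherits(mv, "multiverse_result"), nrow(mv$table) >= 1)
  t <- copy(mv$table)
  t[, class := ifelse(!converged, "nonconverged",
                      ifelse(significant, "significant", "nonsignificant"))]
  t[, spec_order := .I]
  setorder(t, effect_ms, spec_order, na.last = TRUE)
  t[, rank := .I]
  t[class == "nonconverged", effect_ms := NA_real_]
  setcolorder(t, c("rank", "universe_id", "effect_ms", "class"))
  t[, spec_order := NULL]
  t[]
}

#' Decision-dashboard indicator table
#'
#' One row per (decision point, level), one column per universe in
#' specification-curve order; a cell is 1 iff that universe uses that
#' level.  Column sums equal the number of decision points (each universe
#' activates exactly one level per decision); row sums are the factor
#' marginals of the enumeration.
#'
#' @param mv a `multiverse_result`.
#' @return a binary integer matrix with informative dimnames.
#' @export
dashboard_table <- function(mv) {
  stopifnot(inherits(mv, "multiverse_result"), nrow(mv$table) >= 1)
  sc <- specification_curve_table(mv)
  lev <- function(prefix, values) paste0(prefix, ":", values)
  rows <- c(lev("cleaning", unique(sc$cleaning_id)),
            lev("min_fix", sort(unique(sc$min_fixations))),
            lev("outlier", unique(sc[, ifelse(outlier_scope == "none", "none",
                                              paste0(outlier_scope, "_k", outlier_k))])),
            lev("model", unique(sc$model)))
  m <- matrix(0L, nrow = length(rows), ncol = nrow(sc),
              dimnames = list(rows, sc$universe_id))
  olev <- sc[, ifelse(outlier_scope == "none", "none",
                      paste0(outlier_scope, "_k", outlier_k))]
  for (j in seq_len(nrow(sc))) {
    m[paste0("cleaning:", sc$cleaning_id[j]), j] <- 1L
    m[paste0("min_fix:", sc$min_fixations[j]), j] <- 1L
    m[paste0("outlier:", olev[j]), j] <- 1L
    m[paste0("model:", sc$model[j]), j] <- 1L
  }
  m
}

#' Observations-removed versus effect-size table
#'
#' For each cleaning configuration and model family, collects the
#' `(observations removed vs. the no-cleaning baseline, effect in ms)`
#' points of all converged universes and a least-squares slope for
#' orientation (the slope is descriptive only, mirroring lines of best
#' fit added for visualization).
#'
#' @param mv a `multiverse_result`.
#' @return a list with `points` (`data.table`) and `slopes`
#'   (`data.table`: `cleaning_id`, `model`, `n_points`, `slope`; slope is
#'   `NA` when removals do not vary within the panel).
#' @export
removal_vs_effect_table <- function(mv) {
  stopifnot(inherits(mv, "multiverse_result"))
  pts <- mv$table[converged == TRUE,
                  .(cleaning_id, model, n_obs_removed, effect_ms)]
  slopes <- pts[, {
    s <- if (.N >= 2 && stats::var(n_obs_removed) > 0)
      unname(coef(lm(effect_ms ~ n_obs_removed))[2]) else NA_real_
    .(n_points = .N, slope = s)
  }, by = .(cleaning_id, model)]
  list(points = pts[], slopes = slopes[])
}

#' Plot the specification curve and decision dashboard
#'
#' Renders the ordered effect estimates (top) and the decision-level
#' dashboard (bottom) from their tables; no quantity is computed in the
#' plotting layer.
#'
#' @param mv a `multiverse_result`.
#' @param file optional PNG path; when `NULL`, draws on the active device.
#' @return the specification-curve table, invisibly.
#' @export
plot_specification_curve <- function(mv, file = NULL) {
  sc <- specification_curve_table(mv)
  dash <- dashboard_table(mv)
  if (!is.null(file)) {
    grDevices::png(file, width = 1200, height = 900)
    on.exit(grDevices::dev.off())
  }
  op <- graphics::par(mfrow = c(2, 1), mar = c(2, 10, 2, 1))
  on.exit(graphics::par(op), add = TRUE)
  col <- c(significant = "firebrick", nonsignificant = "steelblue",
           nonconverged = "grey60")[sc$class]
  graphics::plot(sc$rank, sc$effect_ms, pch = 19, col = col,
                 xlab = "", ylab = "frequency effect (ms)",
                 main = "specification curve")
  graphics::image(x = seq_len(ncol(dash)), y = seq_len(nrow(dash)),
                  z = t(dash[rev(seq_len(nrow(dash))), , drop = FALSE]),
                  col = c("white", "grey20"), axes = FALSE, xlab = "", ylab = "")
  graphics::axis(2, at = seq_len(nrow(dash)), labels = rev(rownames(dash)),
                 las = 2, cex.axis = 0.6)
  invisible(sc)
}

#' Build a run manifest
#'
#' A reproducibility record: configuration snapshot, seeds, package
#' version, per-stage row counts, and a timestamp.  Everything except the
#' timestamp suffices to regenerate every output byte-identically.
#'
#' @param config named list snapshot of the run configuration.
#' @param seeds named list of seeds used.
#' @param counts named list of per-stage row counts.
#' @return a list of class `run_manifest`.
#' @export
run_manifest <- function(config, seeds, counts = list()) {
  structure(list(package = "fixverse",
                 version = as.character(packageVersion("fixverse")),
                 timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
                 seeds = seeds, counts = counts, config = config),
            class = "run_manifest")
}

#' @rdname run_manifest
#' @param manifest a `run_manifest`.
#' @param path output JSON path.
#' @export
write_run_manifest <- function(manifest, path) {
  jsonlite::write_json(unclass(manifest), path, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(path)
}
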