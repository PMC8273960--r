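# Reference compositions and isotemporal reallocation hazard ratios.
#
# A reallocation displaces delta minutes from one behaviour to another while
# the third behaviour and the waking total stay fixed. Because covariates
# are held at the same values on both sides of the contrast, the log hazard
# ratio is the inner product of the coordinate coefficients with the change
# in ilr coordinates, and its standard error follows from the coordinate
# block of the coefficient covariance (delta method).

#' Build a reference composition anchored on MVPA duration
#'
#' Sets MVPA to `mvpa_min` and splits the remaining waking time between SB
#' and LIPA in proportion `sb_share` : `1 - sb_share`. The conventional
#' anchors are 10, 21 (the 150 min/week guideline, see
#' [guideline_daily_minutes()]) and 30 minutes, with SB taking 77% of the
#' remainder. Fractional minutes are kept exactly.
#'
#' @param mvpa_min MVPA duration in minutes (0 < `mvpa_min` < `total`).
#' @param sb_share Fraction of the non-MVPA waking time assigned to SB.
#' @param total Waking-day total in minutes.
#' @param label Optional label; defaults to `"MVPA=<x>min"`.
#' @return A `"reference_composition"` object: list with `label`,
#'   `composition` (named sb/lipa/mvpa vector summing to `total`), `rule`.
#' @export
#' @examples
#' build_reference_mvpa(21)   # SB 723.03, LIPA 215.97, MVPA 21
build_reference_mvpa <- function(mvpa_min, sb_share = 0.77, total = 960,
                                 label = NULL) {
  if (!is.numeric(mvpa_min) || mvpa_min <= 0 || mvpa_min >= total)
    stop("`mvpa_min` must lie strictly between 0 and `total`", call. = FALSE)
  if (!is.numeric(sb_share) || sb_share <= 0 || sb_share >= 1)
    stop("`sb_share` must lie strictly between 0 and 1", call. = FALSE)
  rem <- total - mvpa_min
  comp <- c(sb = sb_share * rem, lipa = (1 - sb_share) * rem, mvpa = mvpa_min)
  structure(list(
    label = label %||% sprintf("MVPA=%gmin", mvpa_min),
    composition = comp,
    rule = list(type = "mvpa_anchored", mvpa_min = mvpa_min,
                sb_share = sb_share, total = total)
  ), class = "reference_composition")
}

#' Build a reference composition anchored on SB and MVPA durations
#'
#' Sets SB and MVPA directly and assigns LIPA the remaining waking time.
#' The conventional anchors are SB at 9 h and 14 h (5th and 95th cohort
#' percentiles) with MVPA at 10 min.
#'
#' @param sb_min SB duration in minutes.
#' @param mvpa_min MVPA duration in minutes.
#' @param total Waking-day total in minutes.
#' @param label Optional label; defaults to `"SB=<x>min,MVPA=<y>min"`.
#' @return A `"reference_composition"` object.
#' @export
#' @examples
#' build_reference_sb(540, 10)   # LIPA = 410 min (6 h 50 min)
build_reference_sb <- function(sb_min, mvpa_min, total = 960, label = NULL) {
  if (!is.numeric(sb_min) || sb_min <= 0 || !is.numeric(mvpa_min) || mvpa_min <= 0)
    stop("durations must be positive", call. = FALSE)
  lipa <- total - sb_min - mvpa_min
  if (lipa <= 0)
    stop("SB and MVPA leave no waking time for LIPA", call. = FALSE)
  structure(list(
    label = label %||% sprintf("SB=%gmin,MVPA=%gmin", sb_min, mvpa_min),
    composition = c(sb = sb_min, lipa = lipa, mvpa = mvpa_min),
    rule = list(type = "sb_anchored", sb_min = sb_min, mvpa_min = mvpa_min,
                total = total)
  ), class = "reference_composition")
}

#' @export
print.reference_composition <- function(x, ...) {
  cat(sprintf("Reference composition %s: SB %s, LIPA %s, MVPA %s\n",
              x$label, format_hm(x$composition[["sb"]]),
              format_hm(x$composition[["lipa"]]),
              format_hm(x$composition[["mvpa"]])))
  invisible(x)
}

# display-only rounding of fractional minutes to "Xh YYmin"
format_hm <- function(min) {
  r <- round(min)
  sprintf("%dh%02dmin", r %/% 60, r %% 60)
}

ref_composition <- function(ref) {
  if (inherits(ref, "reference_composition")) ref$composition
  else drop(as_comp_matrix(ref)[1, ])
}

#' Displace minutes between two behaviours
#'
#' Moves `delta_min` minutes from `from` to `to`, holding the third
#' behaviour and the waking total fixed. Infeasible displacements (driving
#' the donor behaviour to zero or below) raise an error of class
#' `"ilrsurv_infeasible_reallocation"`; these correspond to the
#' "not observed" cells of a reallocation table.
#'
#' @param ref A `"reference_composition"` or any composition input.
#' @param from,to Behaviour labels (`"sb"`, `"lipa"`, `"mvpa"`).
#' @param delta_min Minutes displaced (nonnegative).
#' @return Named composition vector (sb, lipa, mvpa).
#' @export
#' @examples
#' reallocate(build_reference_mvpa(21), "sb", "mvpa", 10)
reallocate <- function(ref, from, to, delta_min) {
  comp <- ref_composition(ref)
  from <- match.arg(from, behaviours())
  to <- match.arg(to, behaviours())
  if (from == to) stop("`from` and `to` must differ", call. = FALSE)
  if (!is.numeric(delta_min) || delta_min < 0)
    stop("`delta_min` must be nonnegative", call. = FALSE)
  if (delta_min >= comp[[from]])
    stop(errorCondition(
      sprintf("%s cannot be decreased by %g min when its reference value is %g min",
              toupper(from), delta_min, comp[[from]]),
      class = "ilrsurv_infeasible_reallocation"))
  comp[[from]] <- comp[[from]] - delta_min
  comp[[to]] <- comp[[to]] + delta_min
  comp
}

#' Hazard ratio for a time reallocation
#'
#' Contrasts a reallocated composition against its reference under a fitted
#' (or hypothesised) compositional Cox model. With the covariates fixed,
#' `log HR = beta_z . (ilr(reallocated) - ilr(reference))` and
#' `se = sqrt(dz' V_z dz)`; the confidence interval is Wald on the log
#' scale. An infeasible displacement yields a row flagged
#' `feasible = FALSE` with missing estimates rather than an error.
#'
#' @param model A `"comp_cox"` object.
#' @param ref A `"reference_composition"` or composition input.
#' @param from,to Behaviour labels; minutes move from `from` to `to`.
#' @param delta_min Minutes displaced.
#' @param level Confidence level (default 0.95).
#' @return One-row data frame: `reference`, `from`, `to`, `delta_min`,
#'   `hr`, `ci_low`, `ci_high`, `log_hr_se`, `feasible`.
#' @export
#' @examples
#' m <- as_comp_cox(c(0.3, 0.15))
#' reallocation_hr(m, build_reference_mvpa(21), "sb", "mvpa", 10)
reallocation_hr <- function(model, ref, from, to, delta_min, level = 0.95) {
  stopifnot(inherits(model, "comp_cox"))
  comp <- ref_composition(ref)
  lab <- if (inherits(ref, "reference_composition")) ref$label else "custom"
  new <- tryCatch(reallocate(ref, from, to, delta_min),
                  ilrsurv_infeasible_reallocation = function(e) NULL)
  if (is.null(new)) {
    return(data.frame(reference = lab, from = from, to = to,
                      delta_min = delta_min, hr = NA_real_, ci_low = NA_real_,
                      ci_high = NA_real_, log_hr_se = NA_real_,
                      feasible = FALSE))
  }
  dz <- drop(ilr_pivot(new, model$rotation) - ilr_pivot(comp, model$rotation))
  log_hr <- sum(model$beta_z * dz)
  se <- sqrt(drop(t(dz) %*% model$vcov_z %*% dz))
  qz <- stats::qnorm(1 - (1 - level) / 2)
  data.frame(reference = lab, from = from, to = to, delta_min = delta_min,
             hr = exp(log_hr), ci_low = exp(log_hr - qz * se),
             ci_high = exp(log_hr + qz * se), log_hr_se = se,
             feasible = TRUE)
}

#' Reallocation table around one or more references
#'
#' Evaluates [reallocation_hr()] for every ordered behaviour pair and each
#' displacement, mirroring the usual "add 10 min to / remove 10 min from"
#' table layout. Infeasible cells are kept with `feasible = FALSE`.
#'
#' @param model A `"comp_cox"` object.
#' @param refs A `"reference_composition"` or list of them.
#' @param deltas Displacements in minutes (default 10, 20, 30).
#' @param level Confidence level.
#' @return Data frame of reallocation estimates.
#' @export
reallocation_table <- function(model, refs, deltas = c(10, 20, 30),
                               level = 0.95) {
  if (inherits(refs, "reference_composition")) refs <- list(refs)
  rows <- list()
  for (ref in refs) {
    for (d in deltas) {
      for (from in behaviours()) {
        for (to in setdiff(behaviours(), from)) {
          rows[[length(rows) + 1L]] <-
            reallocation_hr(model, ref, from, to, d, level = level)
        }
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Hazard-ratio surface over the simplex
#'
#' Evaluates the hazard ratio of every grid composition against a reference
#' under a fitted model, over a regular minute grid restricted to observed
#' behaviour ranges. The result is a long table renderable as a ternary
#' heatmap with [plot_hr_ternary()].
#'
#' @param model A `"comp_cox"` object.
#' @param ref Reference composition; its own hazard ratio is exactly 1.
#' @param ranges Named list with elements `sb`, `lipa`, `mvpa`, each a
#'   length-2 (min, max) vector of observed minutes; see
#'   [observed_ranges()].
#' @param grid_step Grid spacing in minutes (default 5).
#' @param total Waking-day total in minutes.
#' @return Data frame: `sb_min`, `lipa_min`, `mvpa_min`, `hr`,
#'   `is_reference`; the reference point is appended as its own row.
#' @export
hr_surface <- function(model, ref, ranges, grid_step = 5, total = 960) {
  stopifnot(inherits(model, "comp_cox"))
  comp <- ref_composition(ref)
  if (!is.list(ranges) || !all(behaviours() %in% names(ranges)))
    stop("`ranges` must be a named list with sb, lipa and mvpa entries",
         call. = FALSE)
  grid_seq <- function(r) {
    from <- max(grid_step, r[1]); to <- min(total, r[2])
    if (from > to) numeric(0) else seq(from, to, by = grid_step)
  }
  g <- expand.grid(sb_min = grid_seq(ranges$sb), lipa_min = grid_seq(ranges$lipa))
  if (nrow(g) == 0)
    stop("no grid point satisfies the observed ranges", call. = FALSE)
  g$mvpa_min <- total - g$sb_min - g$lipa_min
  g <- g[g$mvpa_min >= max(grid_step, ranges$mvpa[1]) &
           g$mvpa_min <= ranges$mvpa[2], , drop = FALSE]
  if (nrow(g) == 0)
    stop("no grid point satisfies the observed ranges", call. = FALSE)
  zr <- drop(ilr_pivot(comp, model$rotation))
  z <- ilr_pivot(as.matrix(g[, c("sb_min", "lipa_min", "mvpa_min")]),
                 model$rotation)
  g$hr <- exp((z[, 1] - zr[1]) * model$beta_z[1] +
                (z[, 2] - zr[2]) * model$beta_z[2])
  g$is_reference <- FALSE
  refrow <- data.frame(sb_min = comp[["sb"]], lipa_min = comp[["lipa"]],
                       mvpa_min = comp[["mvpa"]], hr = 1, is_reference = TRUE)
  out <- rbind(g, refrow)
  rownames(out) <- NULL
  out
}

#' Observed behaviour ranges of a cohort
#'
#' @param cohort Cohort data frame with `sb_min`, `lipa_min`, `mvpa_min`.
#' @return Named list of (min, max) minute ranges for `sb`, `lipa`, `mvpa`.
#' @export
observed_ranges <- function(cohort) {
  m <- as_comp_matrix(cohort[, c("sb_min", "lipa_min", "mvpa_min")])
  list(sb = range(m[, "sb"]), lipa = range(m[, "lipa"]),
       mvpa = range(m[, "mvpa"]))
}

#' Ternary heatmap of a hazard-ratio surface
#'
#' Renders the output of [hr_surface()] in ternary coordinates (each vertex
#' a behaviour), coloured by hazard ratio; the reference composition is
#' marked with a black circle. The colour scale is clipped to
#' `hr_limits` for display.
#'
#' @param surface Data frame from [hr_surface()].
#' @param hr_limits Display clip for the hazard-ratio colour scale.
#' @return A ggplot object.
#' @export
plot_hr_ternary <- function(surface, hr_limits = c(0.8, 1.3)) {
  tot <- surface$sb_min + surface$lipa_min + surface$mvpa_min
  # ternary projection: SB bottom-left, LIPA bottom-right, MVPA top
  x <- (surface$lipa_min + 0.5 * surface$mvpa_min) / tot
  y <- (sqrt(3) / 2) * surface$mvpa_min / tot
  df <- data.frame(x = x, y = y,
                   hr = pmin(pmax(surface$hr, hr_limits[1]), hr_limits[2]),
                   is_reference = surface$is_reference)
  ggplot2::ggplot(df[!df$is_reference, ], ggplot2::aes(x = x, y = y)) +
    ggplot2::geom_point(ggplot2::aes(colour = hr), size = 1.2) +
    ggplot2::scale_colour_gradient2(midpoint = 1, low = "#2166ac",
                                    mid = "#f7f7f7", high = "#b2182b",
                                    limits = hr_limits, name = "HR") +
    ggplot2::geom_point(data = df[df$is_reference, ], colour = "black",
                        size = 3, shape = 21, fill = NA, stroke = 1.2) +
    ggplot2::annotate("text", x = c(-0.03, 1.03, 0.5),
                      y = c(-0.03, -0.03, sqrt(3) / 2 + 0.04),
                      label = c("SB", "LIPA", "MVPA")) +
    ggplot2::coord_equal() +
    ggplot2::theme_void()
}

`%||%` <- function(a, b) if (is.null(a)) b else a
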