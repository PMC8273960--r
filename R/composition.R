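# Simplex arithmetic for 3-part waking-day compositions (SB, LIPA, MVPA).

#' Behaviour labels and pivot rotations
#'
#' A waking day is decomposed into three movement behaviours: sedentary
#' behaviour (`sb`), light-intensity physical activity (`lipa`) and
#' moderate-to-vigorous physical activity (`mvpa`). The isometric log-ratio
#' pivot transform can place any one behaviour first, giving three rotations
#' of the same coordinate system:
#'
#' * `"sb_first"`: z1 contrasts SB against the geometric mean of LIPA and
#'   MVPA; z2 contrasts LIPA against MVPA.
#' * `"lipa_first"`: z1 contrasts LIPA against SB and MVPA; z2 contrasts SB
#'   against MVPA.
#' * `"mvpa_first"`: z1 contrasts MVPA against SB and LIPA; z2 contrasts SB
#'   against LIPA.
#'
#' @return `behaviours()` returns the three behaviour labels;
#'   `rotations()` returns a named list mapping each rotation id to its
#'   pivot order.
#' @export
#' @examples
#' behaviours()
#' rotations()$mvpa_first
behaviours <- function() c("sb", "lipa", "mvpa")

#' @rdname behaviours
#' @export
rotations <- function() {
  list(
    sb_first   = c("sb", "lipa", "mvpa"),
    lipa_first = c("lipa", "sb", "mvpa"),
    mvpa_first = c("mvpa", "sb", "lipa")
  )
}

match_rotation <- function(rotation) {
  match.arg(rotation, names(rotations()))
}

# Coerce a composition argument (length-3 vector, matrix or data frame with
# sb/lipa/mvpa columns) to an n x 3 numeric matrix with canonical column order.
as_comp_matrix <- function(x) {
  if (is.data.frame(x)) {
    nm <- names(x)
    cols <- vapply(behaviours(), function(b) {
      hit <- which(nm == b | nm == paste0(b, "_min"))
      if (length(hit) == 0) stop("composition column not found: ", b, call. = FALSE)
      hit[1]
    }, integer(1))
    x <- as.matrix(x[, cols])
    colnames(x) <- behaviours()
  } else if (is.matrix(x)) {
    if (ncol(x) != 3) stop("composition matrix must have 3 columns", call. = FALSE)
    if (!is.null(colnames(x)) && all(behaviours() %in% colnames(x))) {
      x <- x[, behaviours(), drop = FALSE]
    } else {
      colnames(x) <- behaviours()
    }
  } else {
    if (length(x) != 3) stop("a composition has exactly 3 parts", call. = FALSE)
    if (!is.null(names(x)) && all(behaviours() %in% names(x))) x <- x[behaviours()]
    x <- matrix(as.numeric(x), nrow = 1, dimnames = list(NULL, behaviours()))
  }
  storage.mode(x) <- "double"
  x
}

#' Close compositions to a fixed waking-day total
#'
#' Rescales nonnegative (SB, LIPA, MVPA) minutes so each row sums exactly to
#' `total` minutes. The default of 960 minutes corresponds to a 16-hour
#' waking day. The third part is set by subtraction after scaling so the row
#' sum is exact in floating point.
#'
#' @param parts Length-3 numeric vector, n x 3 matrix, or data frame with
#'   `sb`/`lipa`/`mvpa` (or `*_min`) columns; nonnegative minutes per day.
#' @param total Waking-day total in minutes (default 960 = 16 h).
#' @return An n x 3 matrix with columns `sb`, `lipa`, `mvpa`, each row
#'   summing exactly to `total`.
#' @export
#' @examples
#' close_composition(c(700, 200, 100))        # scale factor 0.96
#' close_composition(c(692.1, 209.5, 58.4))   # already sums to 960
close_composition <- function(parts, total = 960) {
  if (!is.numeric(total) || length(total) != 1 || !is.finite(total) || total <= 0)
    stop("`total` must be a single positive number of minutes", call. = FALSE)
  m <- as_comp_matrix(parts)
  if (any(!is.finite(m))) stop("compositions must be finite", call. = FALSE)
  if (any(m < 0)) stop("compositions cannot contain negative minutes", call. = FALSE)
  rs <- rowSums(m)
  if (any(rs == 0)) stop("a composition must have at least one positive part", call. = FALSE)
  out <- m * (total / rs)
  out[, 3] <- total - out[, 1] - out[, 2]
  out
}

#' Isometric log-ratio pivot coordinates
#'
#' Maps each strictly positive 3-part composition to two pivot coordinates
#' under the chosen rotation. With pivot order (a, b, c):
#' `z1 = sqrt(2/3) * log(a / sqrt(b * c))` and `z2 = sqrt(1/2) * log(b / c)`.
#' The transform depends only on ratios, so it is invariant to the closure
#' total.
#'
#' @param comp Composition input as in [close_composition()]; all parts must
#'   be strictly positive (impute zeros first, see [impute_zeros_lrem()]).
#' @param rotation One of `"sb_first"`, `"lipa_first"`, `"mvpa_first"`.
#' @return An n x 2 matrix with columns `z1`, `z2` and attribute
#'   `"rotation"`.
#' @seealso [ilr_pivot_inverse()], [aitchison_distance()]
#' @export
#' @examples
#' ilr_pivot(c(692.1, 209.5, 58.4))           # (1.497, 0.903)
#' ilr_pivot(c(320, 320, 320))                # the barycentre maps to (0, 0)
ilr_pivot <- function(comp, rotation = "sb_first") {
  rotation <- match_rotation(rotation)
  m <- as_comp_matrix(comp)
  if (any(!is.finite(m)) || any(m <= 0))
    stop("all composition parts must be strictly positive; run zero imputation first",
         call. = FALSE)
  ord <- rotations()[[rotation]]
  a <- m[, ord[1]]; b <- m[, ord[2]]; cc <- m[, ord[3]]
  z <- cbind(
    z1 = sqrt(2 / 3) * (log(a) - 0.5 * (log(b) + log(cc))),
    z2 = sqrt(1 / 2) * (log(b) - log(cc))
  )
  rownames(z) <- NULL
  attr(z, "rotation") <- rotation
  z
}

#' Invert pivot coordinates back to minutes
#'
#' Back-transforms ilr pivot coordinates to a composition closed to `total`
#' minutes. Exact inverse of [ilr_pivot()] up to floating-point error.
#'
#' @param z Length-2 numeric vector or n x 2 matrix of (z1, z2) coordinates.
#' @param rotation Rotation the coordinates were computed under; defaults to
#'   the `"rotation"` attribute of `z` if present.
#' @param total Waking-day total in minutes for the returned composition.
#' @return An n x 3 matrix with columns `sb`, `lipa`, `mvpa`.
#' @export
#' @examples
#' ilr_pivot_inverse(c(0, 0))  # (320, 320, 320)
ilr_pivot_inverse <- function(z, rotation = NULL, total = 960) {
  if (is.null(rotation)) rotation <- attr(z, "rotation")
  if (is.null(rotation)) rotation <- "sb_first"
  rotation <- match_rotation(rotation)
  if (!is.matrix(z)) z <- matrix(z, ncol = 2)
  if (ncol(z) != 2) stop("`z` must have two columns (z1, z2)", call. = FALSE)
  if (any(!is.finite(z))) stop("coordinates must be finite", call. = FALSE)
  # with log c fixed at 0: log b = sqrt(2) z2, log a = sqrt(3/2) z1 + log b / 2
  lb <- sqrt(2) * z[, 2]
  la <- sqrt(3 / 2) * z[, 1] + lb / 2
  ord <- rotations()[[rotation]]
  m <- cbind(exp(la), exp(lb), 1)
  colnames(m) <- ord
  close_composition(m[, behaviours(), drop = FALSE], total = total)
}

#' Aitchison distance between compositions
#'
#' Euclidean distance between the ilr images of two compositions. The pivot
#' rotations are orthogonal reparameterisations of the same space, so the
#' distance does not depend on the rotation used.
#'
#' @param c1,c2 Compositions (vector, matrix or data frame) with strictly
#'   positive parts; rows are recycled if one input has a single row.
#' @return Numeric vector of distances.
#' @export
#' @examples
#' aitchison_distance(c(2, 1, 1), c(1, 1, 1))  # sqrt(2/3) * log(2)
aitchison_distance <- function(c1, c2) {
  z1 <- ilr_pivot(c1)
  z2 <- ilr_pivot(c2)
  if (nrow(z1) == 1 && nrow(z2) > 1) z1 <- z1[rep(1, nrow(z2)), , drop = FALSE]
  if (nrow(z2) == 1 && nrow(z1) > 1) z2 <- z2[rep(1, nrow(z1)), , drop = FALSE]
  sqrt(rowSums((z1 - z2)^2))
}

#' Daily equivalent of a weekly activity guideline
#'
#' Converts a weekly MVPA guideline (e.g. the recommended 150 minutes per
#' week) to the whole-minute daily duration used when anchoring reference
#' compositions, `round(weekly_min / 7)`.
#'
#' @param weekly_min Guideline in minutes per week.
#' @return Daily minutes, rounded to the nearest whole minute.
#' @export
#' @examples
#' guideline_daily_minutes(150)  # 21
guideline_daily_minutes <- function(weekly_min = 150) {
  if (!is.numeric(weekly_min) || any(weekly_min <= 0))
    stop("`weekly_min` must be positive", call. = FALSE)
  round(weekly_min / 7)
}
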