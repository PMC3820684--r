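# Overlap between selectivity curves.
#
# The headline competition summary: how much of one gear's size-selection
# coincides with another's. Default measure is the overlap coefficient
# (Weitzman): rescale both curves to unit area on a fine length grid and
# integrate the pointwise minimum — 100% for identical curves, 0% for
# disjoint ones, symmetric by construction.

#' Tabulate selectivity curves on a length grid
#'
#' @param gears A gear tibble, `catch_table` or `selectivity_fit` (see
#'   [curve_summary()]).
#' @param params A [selectivity_params] object (taken from the fit if
#'   omitted).
#' @param lower,upper,step Length grid in cm. The default 0.5-45 cm at
#'   0.01 cm covers the whole observable size range of the bundled data with
#'   negligible tail mass outside.
#' @return A long tibble with columns `length`, `gear`, `selectivity`
#'   (mode-rescaled, so each gear's column peaks at 1 within grid
#'   resolution).
#' @export
curve_table <- function(gears, params = NULL, lower = 0.5, upper = 45,
                        step = 0.01) {
  res <- resolve_gears_params(gears, params)
  g <- res$gears
  grid <- seq(lower, upper, by = step)
  purrr::pmap_dfr(g[c("gear", "family", "mesh_size")],
                  function(gear, family, mesh_size) {
    tibble::tibble(length = grid, gear = gear,
                   selectivity = gear_selectivity(grid, family, mesh_size,
                                                  res$params))
  })
}

trapz_mass <- function(y, step) sum((y[-1] + y[-length(y)]) / 2) * step

#' Overlap between two gears' selectivity curves
#'
#' @inheritParams curve_table
#' @param pairs Either `NULL` (all unordered gear pairs) or a two-column
#'   data frame / list of character pairs naming the gears to compare.
#' @param rescale `"area"` (default): normalise each curve to unit area and
#'   integrate the pointwise minimum (the overlap coefficient).
#'   `"mode"`: keep the curves as drawn, peaking at one, and report
#'   100 x integral(min) / integral(max) — the overlap of the printed
#'   curves relative to their union.
#' @param tail_tol Error if either curve is taller than this fraction of its
#'   modal height at a grid endpoint (the grid would truncate real mass).
#' @return A tibble with columns `gear_a`, `gear_b`, `overlap_pct`, plus the
#'   grid settings as attributes.
#' @examples
#' th <- selectivity_params(0.71, 12.94, 2.13, 0.41)
#' g <- gear_spec(c("G14", "G38", "GC"), c("mesh", "mesh", "predator"),
#'                c(14, 38, NA))
#' curve_overlap(g, th, pairs = list(c("GC", "G38")))
#' @export
curve_overlap <- function(gears, params = NULL, pairs = NULL,
                          rescale = c("area", "mode"),
                          lower = 0.5, upper = 45, step = 0.01,
                          tail_tol = 1e-2) {
  rescale <- match.arg(rescale)
  res <- resolve_gears_params(gears, params)
  g <- res$gears
  grid <- seq(lower, upper, by = step)
  curves <- sapply(seq_len(nrow(g)), function(i) {
    gear_selectivity(grid, g$family[i], g$mesh_size[i], res$params)
  })
  colnames(curves) <- g$gear
  ends <- pmax(curves[1, ], curves[nrow(curves), ])
  if (any(ends > tail_tol)) {
    bad <- names(ends)[ends > tail_tol][1]
    abort(paste0("Grid [", lower, ", ", upper, "] truncates the curve of ",
                 bad, " (endpoint height ", signif(ends[bad], 3),
                 " of modal). Widen the grid, e.g. lower = ",
                 max(0.01, lower / 4), ", upper = ", upper * 2, "."))
  }
  if (is.null(pairs)) {
    idx <- utils::combn(g$gear, 2)
    pairs <- lapply(seq_len(ncol(idx)), function(k) idx[, k])
  } else if (is.data.frame(pairs)) {
    pairs <- lapply(seq_len(nrow(pairs)), function(k) unlist(pairs[k, 1:2]))
  }
  out <- purrr::map_dfr(pairs, function(p) {
    if (!all(p %in% g$gear)) {
      abort(paste0("Unknown gear id(s): ",
                   paste(setdiff(p, g$gear), collapse = ", "),
                   ". Known: ", paste(g$gear, collapse = ", ")))
    }
    a <- curves[, p[1]]
    b <- curves[, p[2]]
    pct <- if (rescale == "area") {
      a <- a / trapz_mass(a, step)
      b <- b / trapz_mass(b, step)
      100 * trapz_mass(pmin(a, b), step)
    } else {
      100 * trapz_mass(pmin(a, b), step) / trapz_mass(pmax(a, b), step)
    }
    tibble::tibble(gear_a = p[1], gear_b = p[2], overlap_pct = pct)
  })
  structure(out, grid = c(lower = lower, upper = upper, step = step),
            rescale = rescale)
}

#' Square overlap matrix for all gears
#'
#' @inheritParams curve_overlap
#' @return A symmetric gear x gear matrix of overlap percentages with 100 on
#'   the diagonal.
#' @export
overlap_matrix <- function(gears, params = NULL, ...) {
  res <- resolve_gears_params(gears, params)
  ov <- curve_overlap(res$gears, res$params, ...)
  ids <- res$gears$gear
  m <- diag(100, length(ids))
  dimnames(m) <- list(ids, ids)
  for (k in seq_len(nrow(ov))) {
    m[ov$gear_a[k], ov$gear_b[k]] <- m[ov$gear_b[k], ov$gear_a[k]] <-
      ov$overlap_pct[k]
  }
  m
}

#' Crossing point of two selectivity curves
#'
#' Length at which two mode-rescaled curves intersect between their modes —
#' e.g. where predation selectivity hands over to a large-mesh net, a value
#' worth comparing with a fishery's minimum legal size.
#'
#' @inheritParams curve_overlap
#' @param pair Character vector of two gear ids.
#' @return The crossing length in cm (the root of the curve difference
#'   between the two modes).
#' @export
crossing_point <- function(gears, params = NULL, pair,
                           lower = 0.5, upper = 45) {
  res <- resolve_gears_params(gears, params)
  g <- res$gears
  if (!all(pair %in% g$gear)) {
    abort(paste0("Unknown gear id(s): ",
                 paste(setdiff(pair, g$gear), collapse = ", ")))
  }
  cs <- curve_summary(g[g$gear %in% pair, ], res$params)
  f <- function(l) {
    i <- match(pair, g$gear)
    gear_selectivity(l, g$family[i[1]], g$mesh_size[i[1]], res$params) -
      gear_selectivity(l, g$family[i[2]], g$mesh_size[i[2]], res$params)
  }
  lo <- min(cs$mode)
  hi <- max(cs$mode)
  if (lo == hi) abort("Curves share a mode; no interior crossing.")
  uniroot(f, c(lo, hi), tol = 1e-8)$root
}
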