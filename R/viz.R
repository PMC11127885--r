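# One-dimensional beeswarm plots of discriminant scores: basic, by survey
# location (geog), and stacked by site phase. Base graphics; the swarm uses a
# deterministic greedy non-overlap placement so identical inputs always give
# identical figures.

#' Deterministic greedy beeswarm offsets
#'
#' Places points one at a time in input order: each point takes the smallest
#' vertical offset (0, +1, -1, +2, ...) at which it does not collide with any
#' already-placed point whose x value is within one point-diameter. Purely
#' deterministic — no jitter, no randomness — so re-plotting identical input
#' is byte-identical.
#'
#' @param x Numeric vector of positions along the swarm axis.
#' @param dx Collision width in `x` units (point diameter); default 1/40 of
#'   the data range.
#' @return Integer vector of stacking offsets (multiply by a display spacing).
#' @export
swarm_offsets <- function(x, dx = NULL) {
  n <- length(x)
  if (!n) return(integer())
  if (is.null(dx)) {
    r <- diff(range(x))
    dx <- if (r > 0) r / 40 else 1
  }
  off <- integer(n)
  for (i in seq_len(n)) {
    near <- which(abs(x[seq_len(i - 1L)] - x[i]) < dx)
    taken <- off[near]
    k <- 0L
    repeat {
      if (!(k %in% taken)) { off[i] <- k; break }
      k <- if (k > 0L) -k else -k + 1L  # 0, 1, -1, 2, -2, ...
    }
  }
  off
}

.layouts <- c("basic", "geog", "phase")

#' Plot discriminant scores against the reference model
#'
#' Draws the archaeobotanical samples' LD1 scores as a one-dimensional
#' beeswarm together with the model's surveyed fields and the two group
#' centroids (group 1 on the positive side by convention). Three layouts:
#'
#' * `basic` — model fields share one symbol; unknowns plotted above them.
#' * `geog` — model fields symbol-coded by survey location, so the regions
#'   pooled into each group stay distinguishable.
#' * `phase` — one stacked subplot per phase label (up to five), shared x
#'   axis, centroids repeated in every subplot; panel order follows first
#'   appearance of each phase in `phase`.
#'
#' @param fit A `wlda` object (provides field scores, locations, centroids).
#' @param results A `weed_classification` data frame for the unknown samples;
#'   may be `NULL`/empty to plot the model alone.
#' @param layout `"basic"`, `"geog"` or `"phase"`.
#' @param phase Character/factor vector of phase labels, one per result row
#'   (phase layout only; at most 5 distinct values).
#' @param file Output path; format from extension (`.svg` or `.png`).
#' @param gpch,gcol,gbg Symbol, colour and fill for the unknown samples
#'   (recycled; in the phase layout, indexed per phase).
#' @param xlim Optional x limits.
#' @param legend_pos Legend keyword (default `"topleft"`), or `NA` to omit.
#' @param compact Swarm collision width in x units (smaller packs tighter).
#' @param width,height Device size in inches.
#' @return Invisibly, a list describing what was drawn (panel names, point
#'   coordinates per panel, centroid positions) — used by tests to introspect
#'   the figure without parsing the file.
#' @export
weed_plot <- function(fit, results = NULL, layout = c("basic", "geog",
                                                      "phase"),
                      phase = NULL, file = NULL,
                      gpch = 21, gcol = "black", gbg = "grey40",
                      xlim = NULL, legend_pos = "topleft", compact = NULL,
                      width = 7, height = 4) {
  stopifnot(inherits(fit, "wlda"))
  layout <- match.arg(layout)
  res <- if (is.null(results)) NULL else as.data.frame(results)
  nres <- if (is.null(res)) 0L else nrow(res)

  if (layout == "phase") {
    if (is.null(phase) || length(phase) != nres)
      stop("phase layout needs one phase label per result row", call. = FALSE)
    phase <- as.character(phase)
    if (anyNA(phase) || any(!nzchar(phase)))
      stop("missing/empty phase labels for samples: ",
           paste(res$sample[is.na(phase) | !nzchar(phase)], collapse = ", "),
           call. = FALSE)
    panels <- unique(phase)  # first-appearance order
    if (length(panels) > 5L)
      stop("at most five phase groups are supported, got ",
           length(panels), call. = FALSE)
  } else {
    panels <- "all"
  }

  mod_x <- fit$training$LD1
  unk_x <- if (nres) res$LD1_unstd else numeric()
  all_x <- c(mod_x, unk_x, fit$centroid_1, fit$centroid_2)
  if (is.null(xlim)) xlim <- range(all_x) + c(-1, 1) * 0.05 * diff(range(all_x))
  if (is.null(compact)) compact <- diff(xlim) / 40

  dev_open <- FALSE
  if (!is.null(file)) {
    ext <- tolower(tools::file_ext(file))
    if (ext == "svg") {
      grDevices::svg(file, width = width, height = height)
    } else if (ext == "png") {
      grDevices::png(file, width = width * 100, height = height * 100,
                     res = 100)
    } else stop("unsupported figure format: .", ext, call. = FALSE)
    dev_open <- TRUE
    on.exit(grDevices::dev.off(), add = TRUE)
  }

  npan <- length(panels)
  op <- graphics::par(mfrow = c(npan, 1L),
                      mar = c(if (npan > 1L) 2.2 else 4, 4, 1.5, 1))
  on.exit(graphics::par(op), add = TRUE)

  locs <- unique(fit$training$location)
  loc_pch <- stats::setNames(c(0, 1, 2, 5, 6, 3, 4)[seq_along(locs)], locs)
  drawn <- list()
  for (pi in seq_len(npan)) {
    pan <- panels[pi]
    sel <- if (layout == "phase") which(phase == pan) else seq_len(nres)
    ux <- unk_x[sel]
    graphics::plot(NA, xlim = xlim, ylim = c(0, 1), yaxt = "n",
                   xlab = if (pi == npan) "LD1 (group 1 positive)" else "",
                   ylab = "", main = if (layout == "phase") pan else NULL)
    spacing <- 0.07
    # model fields swarm around y = 0.25
    m_off <- swarm_offsets(mod_x, compact)
    m_pch <- if (layout == "geog") loc_pch[fit$training$location] else
      ifelse(fit$training$group == 1L, 15, 22)
    graphics::points(mod_x, 0.25 + m_off * spacing, pch = m_pch,
                     col = "grey25", bg = "white", cex = 0.9)
    # unknowns swarm around y = 0.7
    u_off <- swarm_offsets(ux, compact)
    upch <- rep_len(gpch, npan)[pi]
    ucol <- rep_len(gcol, npan)[pi]
    ubg <- rep_len(gbg, npan)[pi]
    if (length(ux))
      graphics::points(ux, 0.7 + u_off * spacing, pch = upch, col = ucol,
                       bg = ubg, cex = 1.1)
    # centroids as vertical ticks (exactly two per panel)
    graphics::points(c(fit$centroid_1, fit$centroid_2), c(0.25, 0.25),
                     pch = 8, cex = 1.6, lwd = 2, col = "black")
    graphics::abline(v = 0, lty = 3, col = "grey70")
    if (pi == 1L && !is.na(legend_pos) && is.character(legend_pos)) {
      if (layout == "geog") {
        graphics::legend(legend_pos, legend = c(locs, "centroid", "samples"),
                         pch = c(unname(loc_pch), 8, upch), cex = 0.7,
                         bty = "n")
      } else {
        graphics::legend(legend_pos,
                         legend = c("group 1 fields", "group 2 fields",
                                    "centroid", "samples"),
                         pch = c(15, 22, 8, upch), cex = 0.7, bty = "n")
      }
    }
    drawn[[pan]] <- list(
      model = data.frame(x = mod_x, y = 0.25 + m_off * spacing,
                         group = fit$training$group,
                         location = fit$training$location),
      unknown = data.frame(x = ux, y = if (length(ux))
        0.7 + u_off * spacing else numeric()),
      centroids = c(group1 = fit$centroid_1, group2 = fit$centroid_2))
  }
  invisible(list(layout = layout, panels = panels, xlim = xlim,
                 file = if (dev_open) file else NULL, drawn = drawn))
}
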