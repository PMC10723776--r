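# Synthetic alley-cropping plot generator. The default parameters reproduce
# the archetypal system used throughout the package: 2 tree lines, each
# planted on an understory vegetation strip carrying 3 trees, separated by
# one cropped alley, with the outside face wrapping the plot.

#' Parameters of a synthetic alley-cropping plot
#'
#' Geometry is plot-local metres: x east, y north, origin at the south-west
#' corner. `n_lines` horizontal understory strips alternate with
#' `n_lines - 1` crop alleys; each strip carries `trees_per_line` square tree
#' faces, regularly spaced, optionally jittered.
#'
#' @param n_lines Number of tree lines (>= 1).
#' @param trees_per_line Trees per line (>= 0).
#' @param strip_width Understory strip width (m).
#' @param alley_width Crop alley width (m).
#' @param tree_size Side of the square tree face (m), < `strip_width`.
#' @param plot_length Plot length along the lines (m).
#' @param jitter Half-range of the uniform jitter on tree centres (m);
#'   0 gives a perfectly regular layout. Clamped so containment and
#'   conformity always hold.
#' @param seed Integer seed driving the jitter (deterministic output).
#' @return An object of class `synth_params`.
#' @export
synth_params <- function(n_lines = 2, trees_per_line = 3, strip_width = 2,
                         alley_width = 12, tree_size = 1, plot_length = 24,
                         jitter = 0, seed = 1L) {
  stopifnot(n_lines >= 1, trees_per_line >= 0,
            strip_width > 0, alley_width > 0, tree_size > 0, plot_length > 0,
            jitter >= 0)
  if (tree_size >= strip_width)
    stop("tree_size must be smaller than strip_width", call. = FALSE)
  if (trees_per_line > 0 && trees_per_line * tree_size >= plot_length)
    stop("trees do not fit along the line", call. = FALSE)
  structure(list(n_lines = as.integer(n_lines),
                 trees_per_line = as.integer(trees_per_line),
                 strip_width = strip_width, alley_width = alley_width,
                 tree_size = tree_size, plot_length = plot_length,
                 jitter = jitter, seed = as.integer(seed)),
            class = "synth_params")
}

#' Generate a synthetic alley-cropping plot specification
#'
#' @param params A [synth_params()] object.
#' @return A [plot_spec()] with `n_lines` strips, `n_lines - 1` alleys and
#'   the trees embedded in their strips; deterministic for a fixed seed.
#' @export
generate_plot <- function(params = synth_params()) {
  stopifnot(inherits(params, "synth_params"))
  p <- params
  areas <- list()
  y <- 0
  strip_ids <- character(p$n_lines)
  for (i in seq_len(p$n_lines)) {
    sid <- sprintf("strip%d", i)
    strip_ids[i] <- sid
    areas[[length(areas) + 1L]] <- plot_area(
      sid, rect_poly(0, y, p$plot_length, y + p$strip_width),
      "understory_strip", list(line = i))
    y <- y + p$strip_width
    if (i < p$n_lines) {
      areas[[length(areas) + 1L]] <- plot_area(
        sprintf("alley%d", i), rect_poly(0, y, p$plot_length, y + p$alley_width),
        "crop", list(alley = i))
      y <- y + p$alley_width
    }
  }
  if (p$trees_per_line > 0) {
    half <- p$tree_size / 2
    pitch <- p$plot_length / p$trees_per_line
    margin_x <- (pitch - p$tree_size) / 2
    margin_y <- (p$strip_width - p$tree_size) / 2
    jmax <- min(p$jitter, 0.49 * margin_x, 0.49 * margin_y)
    jit <- withr::with_seed(p$seed, {
      matrix(stats::runif(2L * p$n_lines * p$trees_per_line, -jmax, jmax),
             ncol = 2)
    })
    k <- 0L
    for (i in seq_len(p$n_lines)) {
      y0 <- (i - 1L) * (p$strip_width + p$alley_width)
      cy <- y0 + p$strip_width / 2
      for (t in seq_len(p$trees_per_line)) {
        k <- k + 1L
        cx <- (t - 0.5) * pitch
        dx <- if (jmax > 0) jit[k, 1] else 0
        dy <- if (jmax > 0) jit[k, 2] else 0
        areas[[length(areas) + 1L]] <- plot_area(
          sprintf("tree%d_%d", i, t),
          rect_poly(cx + dx - half, cy + dy - half, cx + dx + half, cy + dy + half),
          "tree", list(line = i, rank = t), parent = strip_ids[i])
      }
    }
  }
  plot_spec(areas)
}
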