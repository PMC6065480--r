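# Multi-track fusion figures. The default single-fusion layout, top to
# bottom: a superTranscript scale axis, read coverage, gene boundaries,
# protein domains, transcripts (with exon structure) and a sashimi panel
# whose arcs are labeled with split-read support. Expected breakpoints
# are drawn as vertical lines spanning all tracks. A multi-sample variant
# stacks one coverage panel per sample above shared annotation tracks.
#
# PDFs are written uncompressed and their creation/modification dates are
# zeroed after rendering, so identical input yields byte-identical files.

TRACK_NAMES <- c("axis", "coverage", "boundary", "domains", "transcripts",
                 "sashimi")

# colorblind-safe defaults (Okabe-Ito)
FV_PALETTE <- c("#0072B2", "#D55E00", "#009E73", "#E69F00", "#CC79A7",
                "#56B4E9", "#F0E442", "#999999")

#' Figure specification
#'
#' Controls track order, presence, colors and the display threshold of
#' the sashimi panel. Tracks listed in `hide` are dropped; `tracks` must
#' be an ordering of known track names.
#'
#' @param tracks Track order, a permutation (or subset) of
#'   `c("axis", "coverage", "boundary", "domains", "transcripts",
#'   "sashimi")`.
#' @param hide Track names to drop from `tracks`.
#' @param colors Vector of track colors (recycled); defaults to a
#'   colorblind-safe palette.
#' @param min_display_support Minimum junction read support for a sashimi
#'   arc to be drawn (default 3, matching the analysis default).
#' @param format `"pdf"` (vector, deterministic output) or `"png"`.
#' @param width,height Figure size in inches.
#' @return A `figure_spec` list.
#' @export
figure_spec <- function(tracks = TRACK_NAMES, hide = character(0),
                        colors = FV_PALETTE, min_display_support = 3L,
                        format = c("pdf", "png"), width = 8, height = 7) {
  format <- match.arg(format)
  unknown <- setdiff(c(tracks, hide), TRACK_NAMES)
  if (length(unknown) > 0L)
    stop("unknown track name(s): ", paste(unknown, collapse = ", "),
         " (known: ", paste(TRACK_NAMES, collapse = ", "), ")")
  if (anyDuplicated(tracks)) stop("duplicate track names in order")
  structure(list(tracks = setdiff(tracks, hide), colors = colors,
                 min_display_support = min_display_support,
                 format = format, width = width, height = height),
            class = "figure_spec")
}

#' Read a figure specification from YAML or JSON
#'
#' Accepts a config file whose keys mirror the [figure_spec()] arguments
#' (and the corresponding command-line flags).
#'
#' @param path Path to a `.yaml`/`.yml`/`.json` file.
#' @return A `figure_spec`.
#' @export
read_figure_spec <- function(path) {
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = TRUE)
  else yaml::read_yaml(path)
  args <- cfg[intersect(names(cfg), names(formals(figure_spec)))]
  do.call(figure_spec, args)
}

#' Assemble the visualization payload for one fusion
#'
#' Collects everything the figure needs, in fusion coordinates: coverage
#' (one track per sample), gene boundaries, lifted domains and
#' transcripts, junctions and expected breakpoints.
#'
#' @param ref A `fusion_reference`.
#' @param fusion_name Name of the fusion sequence to bundle.
#' @param analyses A single `fusion_analysis` or a named list of them
#'   (one per sample) for multi-sample overlays.
#' @return A `track_bundle`.
#' @export
build_track_bundle <- function(ref, fusion_name, analyses) {
  f <- ref$fusions[[fusion_name]]
  if (is.null(f)) stop("unknown fusion sequence: ", fusion_name)
  if (inherits(analyses, "fusion_analysis")) analyses <- list(analyses)
  if (is.null(names(analyses)) || any(!nzchar(names(analyses))))
    names(analyses) <- paste0("sample", seq_along(analyses))
  coverage <- lapply(analyses, function(a) a$coverage[[fusion_name]])
  if (any(vapply(coverage, is.null, TRUE)))
    stop("analysis lacks coverage for ", fusion_name)
  junctions <- analyses[[1]]$junctions
  junctions <- junctions[junctions$refname == fusion_name, , drop = FALSE]
  L <- nchar(f$sequence)
  boundaries <- data.frame(
    start = c(0L, f$boundary), end = c(f$boundary, L),
    symbol = c(f$st5$symbol, f$st3$symbol), stringsAsFactors = FALSE)
  domains <- rbind(
    f$st5$domains,
    within(f$st3$domains, {start <- start + f$boundary
                           end <- end + f$boundary}))
  transcripts <- c(
    stats::setNames(f$st5$transcripts,
                    paste0(f$st5$symbol, ":", names(f$st5$transcripts))),
    stats::setNames(lapply(f$st3$transcripts, function(tx) {
      tx$start <- tx$start + f$boundary; tx$end <- tx$end + f$boundary; tx
    }), paste0(f$st3$symbol, ":", names(f$st3$transcripts))))
  structure(list(refname = fusion_name, length = L, coverage = coverage,
                 boundaries = boundaries, domains = domains,
                 transcripts = transcripts, junctions = junctions,
                 breakpoints = f$breakpoints, boundary = f$boundary),
            class = "track_bundle")
}

# zero out the PDF timestamps so renders are byte-reproducible
sanitize_pdf <- function(path) {
  txt <- readLines(path, warn = FALSE)
  txt <- gsub("(/CreationDate \\(D:)[0-9]+", "\\100000000000000", txt,
              useBytes = TRUE)
  txt <- gsub("(/ModDate \\(D:)[0-9]+", "\\100000000000000", txt,
              useBytes = TRUE)
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(txt, con, sep = "\n", useBytes = TRUE)
  invisible(path)
}

track_heights <- function(tracks, n_cov = 1L) {
  h <- c(axis = 0.6, coverage = 2.2, boundary = 0.6, domains = 0.7,
         transcripts = 1.6, sashimi = 2.0)
  unlist(lapply(tracks, function(t)
    if (t == "coverage") rep(h[["coverage"]], n_cov) else h[[t]]))
}

draw_breakpoint_lines <- function(bp) {
  if (is.null(bp) || nrow(bp) == 0L) return(invisible())
  grp <- as.integer(factor(paste(bp$donor, bp$acceptor)))
  cols <- FV_PALETTE[(grp - 1L) %% length(FV_PALETTE) + 1L]
  graphics::abline(v = c(bp$donor, bp$acceptor), col = rep(cols, 2L),
                   lty = 2, lwd = 1.2)
}

new_track_panel <- function(L, ylim = c(0, 1)) {
  graphics::par(mar = c(0.3, 5, 0.3, 1))
  graphics::plot(NA, xlim = c(0, L), ylim = ylim, xlab = "", ylab = "",
                 axes = FALSE, xaxs = "i")
}

draw_axis_track <- function(L, bp) {
  new_track_panel(L)
  at <- pretty(c(0, L))
  at <- at[at >= 0 & at <= L]
  graphics::axis(1, at = at, pos = 0.4, cex.axis = 0.7, padj = -1.8,
                 tcl = -0.25)
  graphics::mtext("superTranscript (bp)", side = 2, las = 2, cex = 0.55,
                  line = 0.5)
  draw_breakpoint_lines(bp)
}

draw_coverage_track <- function(track, L, col, bp, label = NULL) {
  depth <- track$depth
  ymax <- max(depth, 1e-9)
  new_track_panel(L, ylim = c(0, ymax * 1.05))
  graphics::polygon(c(0, seq_along(depth) - 0.5, L),
                    c(0, depth, 0), col = col, border = NA)
  graphics::axis(2, at = signif(c(0, ymax), 3), las = 2, cex.axis = 0.6,
                 tcl = -0.2)
  lab <- if (is.null(label))
    if (identical(track$scale, "rpm")) "coverage (RPM)" else "coverage (reads)"
  else label
  graphics::mtext(lab, side = 2, las = 0, cex = 0.55, line = 3)
  draw_breakpoint_lines(bp)
}

draw_boundary_track <- function(boundaries, L, bp) {
  new_track_panel(L)
  for (i in seq_len(nrow(boundaries))) {
    col <- grDevices::adjustcolor(FV_PALETTE[(i - 1L) %% 8L + 1L], 0.35)
    graphics::rect(boundaries$start[i], 0.2, boundaries$end[i], 0.8,
                   col = col, border = "grey30")
    graphics::text((boundaries$start[i] + boundaries$end[i]) / 2, 0.5,
                   boundaries$symbol[i], cex = 0.7)
  }
  graphics::mtext("genes", side = 2, las = 2, cex = 0.55, line = 0.5)
  draw_breakpoint_lines(bp)
}

draw_domains_track <- function(domains, L, bp) {
  new_track_panel(L)
  if (!is.null(domains) && nrow(domains) > 0L) {
    for (i in seq_len(nrow(domains))) {
      graphics::rect(domains$start[i], 0.35, domains$end[i], 0.65,
                     col = FV_PALETTE[[5]], border = NA)
      graphics::text((domains$start[i] + domains$end[i]) / 2, 0.85,
                     domains$name[i], cex = 0.6)
    }
  }
  graphics::mtext("domains", side = 2, las = 2, cex = 0.55, line = 0.5)
  draw_breakpoint_lines(bp)
}

draw_transcripts_track <- function(transcripts, L, bp) {
  n <- max(1L, length(transcripts))
  new_track_panel(L, ylim = c(0, n))
  for (i in seq_along(transcripts)) {
    tx <- transcripts[[i]]
    y <- n - i + 0.5
    graphics::segments(min(tx$start), y, max(tx$end), y, col = "grey40")
    graphics::rect(tx$start, y - 0.25, tx$end, y + 0.25,
                   col = FV_PALETTE[[1]], border = "grey20")
    graphics::text(0, y, names(transcripts)[i], cex = 0.5, adj = c(0, -1.2))
  }
  graphics::mtext("transcripts", side = 2, las = 2, cex = 0.55, line = 0.5)
  draw_breakpoint_lines(bp)
}

draw_sashimi_track <- function(junctions, L, min_support, bp) {
  shown <- junctions[junctions$support >= min_support, , drop = FALSE]
  new_track_panel(L, ylim = c(0, 1.2))
  graphics::segments(0, 0.05, L, 0.05, col = "grey60")
  if (nrow(shown) > 0L) {
    hmax <- max(shown$support)
    for (i in seq_len(nrow(shown))) {
      x0 <- shown$start[i]; x1 <- shown$end[i]
      h <- 0.25 + 0.7 * shown$support[i] / hmax
      t <- seq(0, pi, length.out = 100)
      graphics::lines((x0 + x1) / 2 + (x1 - x0) / 2 * cos(t),
                      0.05 + h * sin(t),
                      col = if (isTRUE(shown$crosses_boundary[i]))
                        FV_PALETTE[[2]] else FV_PALETTE[[1]],
                      lwd = 1 + log2(shown$support[i]))
      graphics::text((x0 + x1) / 2, 0.08 + h, shown$support[i], cex = 0.65)
    }
  }
  graphics::mtext("sashimi", side = 2, las = 2, cex = 0.55, line = 0.5)
  draw_breakpoint_lines(bp)
  shown
}

open_device <- function(path, spec) {
  if (spec$format == "pdf")
    grDevices::pdf(path, width = spec$width, height = spec$height,
                   compress = FALSE, useDingbats = FALSE)
  else
    grDevices::png(path, width = spec$width * 100,
                   height = spec$height * 100, res = 100)
}

#' Render the multi-track figure for one fusion
#'
#' Draws the tracks of `spec$tracks` top to bottom (default: axis,
#' coverage, gene boundary, domains, transcripts, sashimi). Expected
#' breakpoints appear as dashed vertical lines through every track,
#' colored by breakpoint (isoform) group. Sashimi arcs are drawn only for
#' junctions with support at or above `spec$min_display_support` and are
#' labeled with their exact support count. PDF output is
#' byte-deterministic for identical input.
#'
#' @param bundle A `track_bundle`.
#' @param spec A `figure_spec` (default settings when omitted).
#' @param path Output file path.
#' @return Invisibly, a list describing what was drawn: `tracks` (in
#'   order, `"coverage"` repeated per sample), `n_samples`, `arcs` (the
#'   junction rows drawn) and `path`.
#' @export
render_fusion_figure <- function(bundle, spec = figure_spec(), path) {
  stopifnot(inherits(bundle, "track_bundle"), inherits(spec, "figure_spec"))
  L <- bundle$length
  n_cov <- length(bundle$coverage)
  open_device(path, spec)
  on.exit(grDevices::dev.off(), add = TRUE)
  heights <- track_heights(spec$tracks, n_cov)
  n_panel <- length(heights)
  graphics::layout(matrix(seq_len(n_panel), ncol = 1), heights = heights)
  drawn <- character(0)
  arcs <- NULL
  bp <- bundle$breakpoints
  for (tr in spec$tracks) {
    if (tr == "axis") { draw_axis_track(L, bp); drawn <- c(drawn, "axis") }
    else if (tr == "coverage") {
      for (k in seq_len(n_cov)) {
        draw_coverage_track(bundle$coverage[[k]], L,
                            spec$colors[(k - 1L) %% length(spec$colors) + 1L],
                            bp, label = if (n_cov > 1L)
                              names(bundle$coverage)[k] else NULL)
        drawn <- c(drawn, "coverage")
      }
    }
    else if (tr == "boundary") {
      draw_boundary_track(bundle$boundaries, L, bp)
      drawn <- c(drawn, "boundary")
    }
    else if (tr == "domains") {
      draw_domains_track(bundle$domains, L, bp)
      drawn <- c(drawn, "domains")
    }
    else if (tr == "transcripts") {
      draw_transcripts_track(bundle$transcripts, L, bp)
      drawn <- c(drawn, "transcripts")
    }
    else if (tr == "sashimi") {
      arcs <- draw_sashimi_track(bundle$junctions, L,
                                 spec$min_display_support, bp)
      drawn <- c(drawn, "sashimi")
    }
  }
  grDevices::dev.off()
  on.exit()
  if (spec$format == "pdf") sanitize_pdf(path)
  invisible(list(tracks = drawn, n_samples = n_cov, arcs = arcs,
                 path = path))
}

#' Render a multi-sample overlay for one fusion
#'
#' Stacks one coverage panel per sample (shared x axis, RPM scale when
#' available) above the shared annotation tracks (gene boundary, domains,
#' transcripts), with per-isoform breakpoint lines colored by breakpoint
#' group — the layout used to compare one fusion across samples.
#'
#' @param bundles List of `track_bundle`s over the same fusion sequence,
#'   one per sample (or a single bundle already holding several coverage
#'   tracks).
#' @param spec A `figure_spec`.
#' @param path Output file path.
#' @return Invisibly, the draw description as in [render_fusion_figure()].
#' @export
render_multisample_figure <- function(bundles, spec = figure_spec(), path) {
  if (inherits(bundles, "track_bundle")) bundles <- list(bundles)
  refs <- vapply(bundles, `[[`, "", "refname")
  lens <- vapply(bundles, `[[`, 0L, "length")
  if (length(unique(refs)) != 1L)
    stop("bundles cover different reference sequences: ",
         paste(unique(refs), collapse = ", "))
  if (length(unique(lens)) != 1L)
    stop("bundles have mismatched reference lengths")
  merged <- bundles[[1]]
  merged$coverage <- do.call(c, lapply(seq_along(bundles), function(i) {
    cov <- bundles[[i]]$coverage
    if (is.null(names(cov)) || any(!nzchar(names(cov))))
      names(cov) <- paste0("sample", i)
    cov
  }))
  render_fusion_figure(merged, spec, path)
}
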