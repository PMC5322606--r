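# Painted phylograms: branches subdivided into colored segments whose
# lengths are proportional to posterior bin masses.

#' Color specification for painted trees
#'
#' Dwelling mode anchors the 21-step scale at blue (bin 0, 0% dwelling),
#' green (bin 10, 50%) and pure red (bin 20, 100%), interpolated in Lab
#' space; transitions mode uses a perceptually uniform sequential ramp from
#' 0 to the maximum observed count. Unmatched branches are gray.
#'
#' @param mode `"dwelling"` or `"transitions"`.
#' @param colors Optional explicit vector of 21 colors.
#' @param gray Color for branches absent from the posterior.
#' @return A `paint_spec` object.
#' @export
paint_spec <- function(mode = c("dwelling", "transitions"), colors = NULL,
                       gray = "#808080") {
  mode <- match.arg(mode)
  if (is.null(colors)) {
    colors <- if (mode == "dwelling")
      grDevices::colorRampPalette(c("#0000FF", "#00FF00", "#FF0000"),
                                  space = "Lab")(21)
    else grDevices::hcl.colors(21, "Viridis")
  }
  if (length(colors) != 21L) stop_phylomap("need exactly 21 colors")
  structure(list(mode = mode, colors = toupper(colors), gray = toupper(gray)),
            class = "paint_spec")
}

# Rectangular phylogram layout: x = distance from root, y = tip rank.
tree_layout <- function(tree) {
  n <- ape::Ntip(tree)
  x <- ape::node.depth.edgelength(tree)
  y <- numeric(n + tree$Nnode)
  y[seq_len(n)] <- seq_len(n)
  po <- ape::reorder.phylo(tree, "postorder", index.only = TRUE)
  cnt <- numeric(n + tree$Nnode)
  for (e in po) {
    p <- tree$edge[e, 1L]; ch <- tree$edge[e, 2L]
    y[p] <- y[p] + y[ch]; cnt[p] <- cnt[p] + 1
  }
  internal <- (n + 1L):(n + tree$Nnode)
  y[internal] <- y[internal] / pmax(cnt[internal], 1)
  list(x = x, y = y)
}

# Ordered (color, share) segments for one branch: bins by descending mass
# (ties broken by bin index), gray remainder last (tipward).
branch_segments <- function(bin_masses, matched, spec) {
  nz <- which(bin_masses > 0)
  if (length(nz)) {
    ord <- nz[order(-bin_masses[nz], nz)]
    segs <- data.frame(bin = ord - 1L, share = bin_masses[ord],
                       color = spec$colors[ord])
  } else {
    segs <- data.frame(bin = integer(), share = numeric(),
                       color = character())
  }
  gray_share <- max(0, 1 - sum(bin_masses))
  if (gray_share > 1e-12)
    segs <- rbind(segs, data.frame(bin = NA_integer_, share = gray_share,
                                   color = spec$gray))
  segs
}

xml_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  gsub(">", "&gt;", x, fixed = TRUE)
}

legend_labels <- function(spec, summary) {
  if (spec$mode == "dwelling" || summary$quantity == "dwelling_fraction")
    paste0(seq(0, 100, by = 5), "%")
  else format(signif(seq(0, 1, length.out = 21) * summary$scale_max, 4))
}

#' Paint a target tree with posterior bin masses
#'
#' Renders the target tree as a rectangular phylogram in which every branch
#' is subdivided (root-to-tip) into contiguous colored segments: one per
#' occupied bin of the branch's posterior distribution, with segment length
#' proportional to the bin's mass, ordered by descending mass; the
#' unmatched remainder (1 - matched_fraction), if any, is drawn gray at the
#' tipward end. A legend maps bins to colors. SVG output is plain,
#' deterministic XML (segment metadata is kept in `data-*` attributes);
#' `png` and `pdf` use the corresponding graphics devices. A sidecar
#' `<out>.legend.json` records the bin-to-color-to-label mapping.
#'
#' @param target The target `phylo` tree the summary was computed on.
#' @param summary A [summarize_on_target()] result covering the target.
#' @param out Output file path.
#' @param spec A [paint_spec()]; default chosen from the summary's quantity.
#' @param format `"svg"`, `"png"`, or `"pdf"`.
#' @return Invisibly, a list with the output path and the legend table.
#' @export
paint_tree <- function(target, summary, out,
                       spec = NULL, format = c("svg", "png", "pdf")) {
  format <- match.arg(format)
  stopifnot(inherits(summary, "target_summary"))
  spec <- spec %||% paint_spec(
    if (summary$quantity == "dwelling_fraction") "dwelling" else "transitions")
  tgt_ids <- clade_ids(target)
  row <- match(tgt_ids, summary$clade)
  if (anyNA(row))
    stop_phylomap("summary does not cover all target branches")
  lay <- tree_layout(target)
  segs_per_edge <- lapply(seq_along(tgt_ids), function(e)
    branch_segments(summary$bins[row[e], ], summary$matched_fraction[row[e]],
                    spec))
  labels <- legend_labels(spec, summary)
  legend <- data.frame(bin = 0:20, color = spec$colors, label = labels)
  if (format == "svg") {
    write_painted_svg(target, lay, segs_per_edge, tgt_ids, legend, spec, out)
  } else {
    n <- ape::Ntip(target)
    if (format == "png") grDevices::png(out, width = 900, height = 24 * n + 200)
    else grDevices::pdf(out, width = 9, height = (24 * n + 200) / 100)
    on.exit(grDevices::dev.off())
    draw_painted_base(target, lay, segs_per_edge, legend, spec)
  }
  legend_path <- paste0(out, ".legend.json")
  jsonlite::write_json(list(mode = spec$mode, gray = spec$gray,
                            bins = legend),
                       legend_path, auto_unbox = TRUE, digits = NA)
  invisible(list(file = out, legend = legend))
}

write_painted_svg <- function(tree, lay, segs_per_edge, ids, legend, spec,
                              out) {
  n <- ape::Ntip(tree)
  margin <- 20; label_w <- 8 * max(nchar(tree$tip.label)) + 10
  plot_w <- 900 - 2 * margin - label_w
  row_h <- 24
  plot_h <- row_h * n
  height <- plot_h + 2 * margin + 120
  xmax <- max(lay$x); if (xmax <= 0) xmax <- 1
  sx <- function(x) margin + x / xmax * plot_w
  sy <- function(y) margin + (y - 0.5) * row_h
  fmt <- function(x) sprintf("%.3f", x)
  lines <- c(sprintf('<svg xmlns="http://www.w3.org/2000/svg" width="900" height="%d">',
                     ceiling(height)),
             '<g id="connectors">')
  for (e in seq_len(nrow(tree$edge))) {
    p <- tree$edge[e, 1L]; ch <- tree$edge[e, 2L]
    lines <- c(lines, sprintf(
      '<line x1="%s" y1="%s" x2="%s" y2="%s" stroke="#444444" stroke-width="1"/>',
      fmt(sx(lay$x[p])), fmt(sy(lay$y[p])), fmt(sx(lay$x[p])), fmt(sy(lay$y[ch]))))
  }
  lines <- c(lines, "</g>", '<g id="branches">')
  for (e in seq_len(nrow(tree$edge))) {
    p <- tree$edge[e, 1L]; ch <- tree$edge[e, 2L]
    x0 <- sx(lay$x[p]); x1 <- sx(lay$x[ch]); yy <- sy(lay$y[ch])
    segs <- segs_per_edge[[e]]
    pos <- x0
    for (k in seq_len(nrow(segs))) {
      w <- (x1 - x0) * segs$share[k]
      lines <- c(lines, sprintf(
        '<line x1="%s" y1="%s" x2="%s" y2="%s" stroke="%s" stroke-width="5" data-clade="%s" data-bin="%s" data-share="%s"/>',
        fmt(pos), fmt(yy), fmt(pos + w), fmt(yy), segs$color[k],
        xml_escape(ids[e]),
        if (is.na(segs$bin[k])) "gray" else segs$bin[k],
        sprintf("%.6f", segs$share[k])))
      pos <- pos + w
    }
  }
  lines <- c(lines, "</g>", '<g id="tips" font-family="monospace" font-size="12">')
  for (i in seq_len(n))
    lines <- c(lines, sprintf('<text x="%s" y="%s">%s</text>',
                              fmt(sx(lay$x[i]) + 4), fmt(sy(lay$y[i]) + 4),
                              xml_escape(tree$tip.label[i])))
  ly <- margin + plot_h + 30
  lines <- c(lines, "</g>", '<g id="legend" font-family="monospace" font-size="10">')
  for (k in seq_len(21)) {
    lx <- margin + (k - 1) * 24
    lines <- c(lines, sprintf(
      '<rect x="%s" y="%s" width="24" height="14" fill="%s" data-bin="%d"/>',
      fmt(lx), fmt(ly), legend$color[k], legend$bin[k]))
    if (k %in% c(1, 11, 21))
      lines <- c(lines, sprintf('<text x="%s" y="%s">%s</text>',
                                fmt(lx), fmt(ly + 28),
                                xml_escape(legend$label[k])))
  }
  lines <- c(lines, sprintf(
    '<rect x="%s" y="%s" width="24" height="14" fill="%s" data-bin="gray"/>',
    fmt(margin + 21 * 24 + 12), fmt(ly), spec$gray),
    sprintf('<text x="%s" y="%s">unmatched</text>',
            fmt(margin + 21 * 24 + 12), fmt(ly + 28)),
    "</g>", "</svg>")
  writeLines(lines, out)
  invisible(out)
}

draw_painted_base <- function(tree, lay, segs_per_edge, legend, spec) {
  n <- ape::Ntip(tree)
  xmax <- max(lay$x); if (xmax <= 0) xmax <- 1
  graphics::par(mar = c(6, 1, 1, 8), xpd = NA)
  graphics::plot(NA, xlim = c(0, xmax * 1.05), ylim = c(0.5, n + 0.5),
                 axes = FALSE, xlab = "", ylab = "")
  for (e in seq_len(nrow(tree$edge))) {
    p <- tree$edge[e, 1L]; ch <- tree$edge[e, 2L]
    graphics::segments(lay$x[p], lay$y[p], lay$x[p], lay$y[ch],
                       col = "#444444")
    segs <- segs_per_edge[[e]]
    pos <- lay$x[p]
    for (k in seq_len(nrow(segs))) {
      w <- (lay$x[ch] - lay$x[p]) * segs$share[k]
      graphics::segments(pos, lay$y[ch], pos + w, lay$y[ch],
                         col = segs$color[k], lwd = 5, lend = 1)
      pos <- pos + w
    }
  }
  for (i in seq_len(n))
    graphics::text(lay$x[i], lay$y[i], tree$tip.label[i], pos = 4, cex = 0.8)
  # legend strip under the tree
  lx <- seq(0, xmax, length.out = 22)
  for (k in seq_len(21))
    graphics::rect(lx[k], -0.08 * n, lx[k + 1], -0.03 * n,
                   col = legend$color[k], border = NA)
  graphics::text(c(lx[1], lx[11], lx[21]), rep(-0.12 * n, 3),
                 legend$label[c(1, 11, 21)], cex = 0.7)
}
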