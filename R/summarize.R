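# Posterior summarization onto a target topology: clade matching and
# 5%-step tonality binning.

#' Bin a dwelling fraction into 5% tonality steps
#'
#' Fractions are rounded to the nearest multiple of 5%: bin k (k = 0..20)
#' covers ((k - 0.5) * 5%, (k + 0.5) * 5%], with bin 0 = \[0, 2.5%\] and bin
#' 20 = (97.5%, 100%\]. Bin 20 is the "100%" tone (pure red on the dwelling
#' color scale), bin 0 the "0%" tone.
#'
#' @param fraction Numeric vector in \[0, 1\].
#' @return Integer bin indices in 0..20.
#' @export
bin_dwelling_fraction <- function(fraction) {
  if (any(!is.finite(fraction)) || any(fraction < 0) || any(fraction > 1))
    stop_phylomap("dwelling fractions must lie in [0, 1]")
  pmax(0L, as.integer(ceiling(fraction * 20 - 0.5)))
}

# Bin a non-negative quantity onto 21 equal-width bins over [0, scale_max],
# nearest-bin-center convention as above. scale_max = 0 puts everything in
# bin 0.
bin_on_scale <- function(x, scale_max) {
  if (scale_max <= 0) return(rep(0L, length(x)))
  pmin(20L, pmax(0L, as.integer(ceiling(x / scale_max * 20 - 0.5))))
}

#' Summarize per-branch expectations from a posterior onto a target tree
#'
#' For each branch of the target tree (identified by its clade tip-set) the
#' matching branch is looked up in every posterior tree; each match
#' contributes weight 1/t (t = number of posterior trees) to the bin of its
#' per-branch quantity. Dwelling fractions are binned in 5% steps
#' ([bin_dwelling_fraction()]); transition counts are binned on 21
#' equal-width bins spanning 0 to the maximum observed over all matched
#' branches. Trees lacking the clade contribute to `1 - matched_fraction`;
#' a branch matched by no tree is flagged gray.
#'
#' @param target A rooted `phylo` tree sharing the taxon namespace.
#' @param trees The posterior `treeset` the mappings came from.
#' @param mappings A `mapping_set` (or list of `mapping_result`), one per
#'   posterior tree.
#' @param state State label (or index) whose quantity is summarized.
#' @param quantity `"dwelling_fraction"` or `"transitions"` (expected
#'   transitions away from `state`).
#' @param renormalize If `TRUE`, bin distributions of partially matched
#'   branches are renormalized to sum to 1; by default they sum to
#'   `matched_fraction` and the remainder is painted gray along the branch.
#' @return A `target_summary`: list with `clade`, `matched_fraction`,
#'   `bins` (branches x 21 matrix of masses), `gray` (logical),
#'   `quantity`, `state`, `scale_max` (transitions mode), `renormalized`.
#' @export
summarize_on_target <- function(target, trees, mappings, state,
                                quantity = c("dwelling_fraction", "transitions"),
                                renormalize = FALSE) {
  quantity <- match.arg(quantity)
  if (inherits(mappings, "mapping_result")) mappings <- list(mappings)
  trees <- as_treeset(trees)
  if (length(mappings) != length(trees))
    stop_phylomap("need one mapping per posterior tree (",
                  length(mappings), " vs ", length(trees), ")")
  if (!setequal(target$tip.label, trees[[1L]]$tip.label))
    stop_phylomap("target tree does not share the posterior's taxon namespace")
  tgt_ids <- clade_ids(target)
  t_n <- length(mappings)

  # Collect, per target branch, the quantity value in each posterior tree
  # that contains the clade.
  values <- vector("list", length(tgt_ids))
  for (k in seq_len(t_n)) {
    m <- mappings[[k]]
    if (is.null(m)) next
    st <- if (is.character(state)) match(state, m$states) else as.integer(state)
    if (is.na(st) || st < 1L || st > length(m$states))
      stop_phylomap("unknown state: ", state)
    v <- if (quantity == "dwelling_fraction") m$dwell_frac[, st] else m$away[, st]
    hit <- match(tgt_ids, m$clade)
    ok <- which(!is.na(hit))
    for (b in ok) values[[b]] <- c(values[[b]], v[hit[b]])
  }

  summarize_values(tgt_ids, values, t_n, quantity,
                   state = as.character(state),
                   renormalize = renormalize, target = target)
}

# Shared binning core: values is a list (per target branch) of matched
# per-tree quantity values; t_n the posterior size.
summarize_values <- function(tgt_ids, values, t_n, quantity, state,
                             renormalize = FALSE, target = NULL) {
  scale_max <- if (quantity == "transitions") {
    mx <- suppressWarnings(max(unlist(values), 0))
    if (!is.finite(mx)) 0 else mx
  } else NA_real_

  bins <- matrix(0, length(tgt_ids), 21L,
                 dimnames = list(NULL, paste0("bin", 0:20)))
  matched <- numeric(length(tgt_ids))
  for (b in seq_along(tgt_ids)) {
    v <- values[[b]]
    if (is.null(v) || !length(v)) next
    idx <- if (quantity == "dwelling_fraction")
      bin_dwelling_fraction(pmin(pmax(v, 0), 1))
    else bin_on_scale(v, scale_max)
    bins[b, ] <- tabulate(idx + 1L, 21L) / t_n  # one division: exact masses
    matched[b] <- length(v) / t_n
  }
  if (renormalize) {
    nz <- matched > 0
    bins[nz, ] <- bins[nz, , drop = FALSE] / matched[nz]
  }
  structure(list(clade = tgt_ids, matched_fraction = matched, bins = bins,
                 gray = matched == 0, quantity = quantity,
                 state = as.character(state), scale_max = scale_max,
                 renormalized = renormalize, target = target),
            class = "target_summary")
}

#' Summarize a serialized mapping table onto a target tree
#'
#' Same operation as [summarize_on_target()], but starting from the TSV
#' representation produced by [write_mapping_tsv()] (columns `tree`,
#' `clade`, `dwell_frac_<state>`, `away_<state>`), so a posterior can be
#' summarized without re-running the mapping.
#'
#' @param target A rooted `phylo` target tree.
#' @param table A data frame as returned by [read_mapping_tsv()].
#' @param state State label.
#' @param quantity `"dwelling_fraction"` or `"transitions"`.
#' @param renormalize See [summarize_on_target()].
#' @return A `target_summary`.
#' @export
summarize_mapping_table <- function(target, table, state,
                                    quantity = c("dwelling_fraction",
                                                 "transitions"),
                                    renormalize = FALSE) {
  quantity <- match.arg(quantity)
  col <- paste0(if (quantity == "dwelling_fraction") "dwell_frac_"
                else "away_", state)
  if (!col %in% names(table))
    stop_phylomap("mapping table lacks column ", col)
  t_n <- length(unique(table$tree))
  tgt_ids <- clade_ids(target)
  values <- vector("list", length(tgt_ids))
  hit <- split(as.numeric(table[[col]]), table$clade)
  for (b in seq_along(tgt_ids)) {
    v <- hit[[tgt_ids[b]]]
    if (!is.null(v)) values[[b]] <- v
  }
  summarize_values(tgt_ids, values, t_n, quantity,
                   state = as.character(state),
                   renormalize = renormalize, target = target)
}

#' @export
print.target_summary <- function(x, ...) {
  cat("target_summary (", x$quantity, ", state ", x$state, "): ",
      length(x$clade), " target branches, ", sum(x$gray), " gray\n", sep = "")
  if (x$quantity == "transitions")
    cat("transition scale: 0 to", signif(x$scale_max, 5), "\n")
  invisible(x)
}

#' Write / read a target summary as TSV
#'
#' One row per target branch: clade ID, matched fraction, gray flag, and the
#' 21 bin masses. Scale metadata is kept in `#`-prefixed header comments.
#'
#' @param summary A `target_summary`.
#' @param path Output TSV path.
#' @export
write_summary_tsv <- function(summary, path) {
  stopifnot(inherits(summary, "target_summary"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(paste0("# quantity=", summary$quantity),
               paste0("# state=", summary$state),
               paste0("# scale_max=", format(summary$scale_max, digits = 15)),
               paste0("# renormalized=", summary$renormalized)), con)
  df <- data.frame(clade = summary$clade,
                   matched_fraction = summary$matched_fraction,
                   gray = as.integer(summary$gray), check.names = FALSE)
  df <- cbind(df, as.data.frame(summary$bins))
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_summary_tsv
#' @return `read_summary_tsv()` restores a `target_summary` (without the
#'   target tree, which is supplied separately where needed).
#' @export
read_summary_tsv <- function(path) {
  lines <- readLines(path)
  meta <- grep("^# ", lines, value = TRUE)
  kv <- do.call(rbind, strsplit(sub("^# ", "", meta), "=", fixed = TRUE))
  vals <- stats::setNames(kv[, 2L], kv[, 1L])
  df <- utils::read.delim(text = lines[!startsWith(lines, "#")],
                          sep = "\t", check.names = FALSE)
  bins <- as.matrix(df[, paste0("bin", 0:20)])
  structure(list(clade = df$clade,
                 matched_fraction = df$matched_fraction,
                 bins = bins, gray = df$gray == 1,
                 quantity = vals[["quantity"]], state = vals[["state"]],
                 scale_max = if (vals[["scale_max"]] %in% c("NA", "NaN"))
                   NA_real_ else as.numeric(vals[["scale_max"]]),
                 renormalized = vals[["renormalized"]] == "TRUE",
                 target = NULL),
            class = "target_summary")
}
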