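#' Read a set of rooted trees from Newick or NEXUS
#'
#' Trees are read as written: the file's rooting is honored and no rerooting
#' is performed (clade matching downstream is root-dependent). NEXUS
#' `TRANSLATE` tables are resolved to taxon names by the reader. All trees in
#' the file must share the same tip-label set; this is what makes the set a
#' coherent posterior sample over one taxon namespace.
#'
#' @param path Path to a tree file.
#' @param format `"newick"`, `"nexus"`, or `"auto"` (sniff for a `#NEXUS`
#'   header).
#' @return An object of class `c("treeset", "multiPhylo")`: a list of `phylo`
#'   trees in input order.
#' @export
read_trees <- function(path, format = c("auto", "newick", "nexus")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop_phylomap("tree file not found: ", path)
  if (format == "auto") {
    head1 <- toupper(trimws(readLines(path, n = 1L, warn = FALSE)))
    format <- if (length(head1) && startsWith(head1, "#NEXUS")) "nexus" else "newick"
  }
  trees <- tryCatch(
    if (format == "nexus") ape::read.nexus(path) else ape::read.tree(path),
    error = function(e) stop_phylomap("failed to parse '", path, "' as ",
                                      format, ": ", conditionMessage(e)))
  if (inherits(trees, "phylo")) trees <- c(trees)  # promote to multiPhylo
  if (is.null(trees) || length(trees) == 0L)
    stop_phylomap("no trees found in ", path)
  as_treeset(trees)
}

#' Assemble a validated tree set
#'
#' @param trees A `phylo`, `multiPhylo`, or list of `phylo` objects.
#' @return A `c("treeset", "multiPhylo")` object.
#' @export
as_treeset <- function(trees) {
  if (inherits(trees, "phylo")) trees <- list(trees)
  trees <- unclass(trees)
  stopifnot(length(trees) >= 1L)
  ref <- sort(trees[[1L]]$tip.label)
  for (i in seq_along(trees)) {
    ti <- trees[[i]]
    if (!inherits(ti, "phylo")) stop_phylomap("element ", i, " is not a phylo tree")
    if (anyDuplicated(ti$tip.label))
      stop_phylomap("tree ", i, " has duplicated tip labels")
    if (!is.null(ti$edge.length) && any(ti$edge.length < 0))
      stop_phylomap("tree ", i, " has negative edge lengths")
    if (!identical(sort(ti$tip.label), ref))
      stop_phylomap("tree ", i, " has a different tip-label set from tree 1")
  }
  structure(trees, class = c("treeset", "multiPhylo"))
}

#' Write a tree set to Newick or NEXUS
#'
#' @param trees A `treeset`/`multiPhylo`/`phylo`.
#' @param path Output path.
#' @param format `"newick"` or `"nexus"`.
#' @export
write_trees <- function(trees, path, format = c("newick", "nexus")) {
  format <- match.arg(format)
  if (inherits(trees, "phylo")) trees <- as_treeset(trees)
  class(trees) <- "multiPhylo"
  if (format == "nexus") ape::write.nexus(trees, file = path)
  else ape::write.tree(trees, file = path, digits = 15)
  invisible(path)
}

#' Construct discrete character data over an ordered state alphabet
#'
#' Each taxon is assigned a non-empty subset of the alphabet: a singleton for
#' an observed state, the full alphabet for missing data, a proper subset for
#' partial ambiguity.
#'
#' @param assignments Named list (taxon -> character vector of states) or a
#'   named character vector of state strings using the TSV conventions:
#'   a plain state, `?` for full missingness, or a `/`-joined set.
#' @param alphabet Ordered character vector of state labels (length >= 2). If
#'   `NULL`, the sorted set of states seen in unambiguous assignments.
#' @return A `character_data` object with fields `alphabet` and `matrix`
#'   (taxa x states 0/1 indicator of allowed states).
#' @export
character_data <- function(assignments, alphabet = NULL) {
  if (is.character(assignments) || is.factor(assignments)) {
    v <- stats::setNames(as.character(assignments), names(assignments))
    assignments <- lapply(v, function(x)
      if (identical(x, "?")) NA_character_
      else strsplit(x, "/", fixed = TRUE)[[1L]])
  }
  if (is.null(names(assignments)) || anyDuplicated(names(assignments)))
    stop_phylomap("assignments must be uniquely named by taxon")
  assignments <- lapply(assignments, as.character)
  if (any(lengths(assignments) == 0L))
    stop_phylomap("empty state assignment for: ",
                  paste(names(assignments)[lengths(assignments) == 0L], collapse = ", "))
  full <- vapply(assignments, anyNA, TRUE)  # "?": resolved once alphabet known
  if (is.null(alphabet)) {
    singletons <- unlist(assignments[!full & lengths(assignments) == 1L],
                         use.names = FALSE)
    alphabet <- sort(unique(singletons))
  }
  assignments[full] <- list(as.character(alphabet))
  alphabet <- as.character(alphabet)
  if (length(alphabet) < 2L)
    stop_phylomap("state alphabet must have at least 2 states, got ",
                  length(alphabet))
  bad <- setdiff(unique(unlist(assignments)), alphabet)
  if (length(bad))
    stop_phylomap("states not in alphabet: ", paste(bad, collapse = ", "))
  m <- matrix(0, nrow = length(assignments), ncol = length(alphabet),
              dimnames = list(names(assignments), alphabet))
  for (i in seq_along(assignments)) m[i, assignments[[i]]] <- 1
  structure(list(alphabet = alphabet, matrix = m),
            class = "character_data")
}

#' @export
print.character_data <- function(x, ...) {
  cat("character_data:", nrow(x$matrix), "taxa,",
      length(x$alphabet), "states (", paste(x$alphabet, collapse = ", "), ")\n")
  n_amb <- sum(rowSums(x$matrix) > 1)
  if (n_amb) cat("  ", n_amb, "taxa with ambiguous/missing assignments\n")
  invisible(x)
}

#' Read a tip-state table
#'
#' Expects a TSV with a header and columns `taxon` and `state`. The state
#' cell may be `?` (fully missing) or a `/`-separated set such as `a/b`
#' (ambiguity among the listed states).
#'
#' @param path Path to the TSV file.
#' @param alphabet Optional explicit ordered alphabet; defaults to the sorted
#'   set of unambiguous states observed.
#' @param taxa Optional character vector of required taxa (e.g. a tree's tip
#'   labels); taxa in the table but not in `taxa` raise a validation error,
#'   as do required taxa missing from the table.
#' @return A [character_data()] object.
#' @export
read_tip_states <- function(path, alphabet = NULL, taxa = NULL) {
  if (!file.exists(path)) stop_phylomap("tip-state file not found: ", path)
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           colClasses = "character", check.names = FALSE)
  if (!all(c("taxon", "state") %in% names(tab)))
    stop_phylomap("tip-state table must have columns 'taxon' and 'state'")
  if (any(trimws(tab$state) == ""))
    stop_phylomap("empty state cell for taxon: ",
                  paste(tab$taxon[trimws(tab$state) == ""], collapse = ", "))
  if (!is.null(taxa)) {
    extra <- setdiff(tab$taxon, taxa)
    missing <- setdiff(taxa, tab$taxon)
    if (length(extra))
      stop_phylomap("taxa absent from the tree namespace: ",
                    paste(extra, collapse = ", "))
    if (length(missing))
      stop_phylomap("taxa without a state assignment: ",
                    paste(missing, collapse = ", "))
  }
  if (is.null(alphabet)) {
    plain <- tab$state[tab$state != "?" & !grepl("/", tab$state, fixed = TRUE)]
    alphabet <- sort(unique(plain))
  }
  assignments <- lapply(tab$state, function(s) {
    if (s == "?") alphabet else strsplit(s, "/", fixed = TRUE)[[1L]]
  })
  names(assignments) <- tab$taxon
  character_data(assignments, alphabet = alphabet)
}

#' Write a tip-state table
#'
#' Inverse of [read_tip_states()]: singletons as plain states, full ambiguity
#' as `?`, partial ambiguity as `/`-joined sets.
#'
#' @param data A `character_data` object.
#' @param path Output TSV path.
#' @export
write_tip_states <- function(data, path) {
  stopifnot(inherits(data, "character_data"))
  s <- length(data$alphabet)
  cells <- apply(data$matrix, 1L, function(row) {
    st <- data$alphabet[row > 0]
    if (length(st) == s) "?" else paste(st, collapse = "/")
  })
  utils::write.table(data.frame(taxon = rownames(data$matrix), state = cells),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Index the clades of a rooted tree
#'
#' Maps every non-root node (equivalently, every branch, identified by its
#' child node) to the set of tip labels descended from it. This tip-set is
#' the key used to decide whether two rooted trees on the same taxon
#' namespace contain "the same branch".
#'
#' @param tree A rooted `phylo` tree.
#' @return A `clade_index` object: list with `node` (child node numbers, one
#'   per edge, in `tree$edge` order), `tips` (list of tip-label vectors), and
#'   `id` (canonical clade identifier: sorted tips joined by `|`).
#' @export
clade_index <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  if (!ape::is.rooted(tree)) stop_phylomap("clade_index requires a rooted tree")
  n <- ape::Ntip(tree)
  nn <- n + tree$Nnode
  desc <- vector("list", nn)
  for (i in seq_len(n)) desc[[i]] <- tree$tip.label[i]
  po <- ape::reorder.phylo(tree, "postorder", index.only = TRUE)
  for (e in po) {
    p <- tree$edge[e, 1L]; ch <- tree$edge[e, 2L]
    desc[[p]] <- c(desc[[p]], desc[[ch]])
  }
  child <- tree$edge[, 2L]
  tips <- lapply(desc[child], sort)
  structure(list(node = child,
                 tips = tips,
                 id = vapply(tips, paste, "", collapse = "|")),
            class = "clade_index")
}

#' @rdname clade_index
#' @return `clade_ids()` returns just the canonical clade-ID strings, one
#'   per edge, in `tree$edge` order.
#' @export
clade_ids <- function(tree) clade_index(tree)$id
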