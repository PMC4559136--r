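format_num <- function(x) {
  # fixed, locale-independent rendering with trailing zeros trimmed
  out <- formatC(x, format = "f", digits = 6)
  out <- sub("0+$", "", out)
  sub("\\.$", ".0", out)
}

phylip_labels <- function(labels) {
  trunc <- substr(labels, 1, 10)
  if (anyDuplicated(trunc))
    rlang::abort(paste0("labels collide after truncation to 10 characters: ",
                        paste(unique(trunc[duplicated(trunc)]),
                              collapse = ", ")))
  formatC(trunc, width = 10, flag = "-")
}

#' Export a dissimilarity matrix as text
#'
#' `phylip`: square Phylip distance format (taxon count, then one padded
#' 10-character label plus row values per line; truncation collisions are an
#' error). `tsv`: tab-separated square matrix with a header and a leading
#' `taxon` column. `r`: text readable back into R with
#' `dget()`/`as.dist()`.
#'
#' @param D A `glyco_dissimilarity` (or plain labelled matrix).
#' @param format `"phylip"`, `"tsv"` or `"r"`.
#' @return A single character string (with trailing newline).
#' @export
#' @examples
#' m <- matrix(c(0, 100, 100, 0), 2, dimnames = list(c("A", "B"), c("A", "B")))
#' cat(export_matrix(m, "phylip"))
export_matrix <- function(D, format = c("phylip", "tsv", "r")) {
  format <- match.arg(format)
  m <- as.matrix(unclass(D))
  labels <- rownames(m)
  if (is.null(labels)) rlang::abort("matrix has no taxon labels")
  if (format == "phylip") {
    rows <- vapply(seq_len(nrow(m)), function(i) {
      paste0(phylip_labels(labels)[i], " ",
             paste(format_num(m[i, ]), collapse = " "))
    }, character(1))
    return(paste0(nrow(m), "\n", paste(rows, collapse = "\n"), "\n"))
  }
  if (format == "tsv") {
    header <- paste(c("taxon", labels), collapse = "\t")
    rows <- vapply(seq_len(nrow(m)), function(i) {
      paste(c(labels[i], format_num(m[i, ])), collapse = "\t")
    }, character(1))
    return(paste0(header, "\n", paste(rows, collapse = "\n"), "\n"))
  }
  # r: dget()-compatible dump of the labelled numeric matrix
  con <- textConnection("out", "w", local = TRUE)
  dput(m, file = con)
  close(con)
  paste0(paste(out, collapse = "\n"), "\n")
}

#' Export a tree as Newick or Nexus text
#'
#' Newick carries branch lengths; the Nexus output is a minimal TAXA +
#' TREES block (with a translate table) whose tree line is the same Newick
#' string, deterministic for identical trees.
#'
#' @param tree A `phylo` object.
#' @param format `"newick"` or `"nexus"`.
#' @return A single character string.
#' @export
export_tree <- function(tree, format = c("newick", "nexus")) {
  format <- match.arg(format)
  stopifnot(inherits(tree, "phylo"))
  if (format == "newick")
    return(paste0(ape::write.tree(tree), "\n"))
  labels <- tree$tip.label
  tr <- tree
  tr$tip.label <- as.character(seq_along(labels))
  translate <- paste0("\t\t", seq_along(labels), " ", labels,
                      c(rep(",", length(labels) - 1L), ""))
  rooted_tag <- if (ape::is.rooted(tree)) "[&R] " else "[&U] "
  paste0("#NEXUS\n",
         "BEGIN TAXA;\n",
         "\tDIMENSIONS NTAX=", length(labels), ";\n",
         "\tTAXLABELS\n",
         paste0("\t\t", labels, collapse = "\n"), "\n\t;\nEND;\n",
         "BEGIN TREES;\n",
         "\tTRANSLATE\n", paste(translate, collapse = "\n"), "\n\t;\n",
         "\tTREE tree1 = ", rooted_tag, ape::write.tree(tr), "\n",
         "END;\n")
}

#' Write all artifacts of a clustering run to a directory
#'
#' Writes the dissimilarity matrix in the chosen format, the tree in Newick
#' and/or Nexus, a coverage table of the used taxa, and a `params.txt` dump
#' of every parameter of the run (sufficient to reproduce it bit-identically
#' from the same dump file).
#'
#' @param result A `glyco_clustering` object.
#' @param dir Output directory (created if missing).
#' @param matrix_format `"phylip"`, `"tsv"` or `"r"`.
#' @param tree_format `"newick"`, `"nexus"` or `"both"`.
#' @return Character vector of written paths, invisibly.
#' @export
write_clustering <- function(result, dir, matrix_format = "tsv",
                             tree_format = "newick") {
  stopifnot(inherits(result, "glyco_clustering"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character()
  wr <- function(text, name) {
    p <- file.path(dir, name)
    writeLines(text, p, sep = "")
    paths <<- c(paths, p)
  }
  ext <- c(phylip = "phy", tsv = "tsv", r = "R")[[matrix_format]]
  wr(export_matrix(result$matrix, matrix_format), paste0("matrix.", ext))
  if (tree_format %in% c("newick", "both"))
    wr(export_tree(result$tree, "newick"), "tree.nwk")
  if (tree_format %in% c("nexus", "both"))
    wr(export_tree(result$tree, "nexus"), "tree.nex")
  cov <- result$taxon_pool
  wr(paste0(paste(c("taxon\tn_structures",
                    paste(cov$taxon, cov$n_structures, sep = "\t")),
                  collapse = "\n"), "\n"), "taxa_coverage.tsv")
  frag <- result$fragment_pool
  wr(paste0(paste(c("fragment\tn_structures\tn_instances",
                    paste(frag$fragment, frag$n_structures,
                          frag$n_instances, sep = "\t")),
                  collapse = "\n"), "\n"), "fragment_pool.tsv")
  th <- result$params$thresholds
  opts <- result$params$opts
  par_lines <- c(
    paste0("rank=", result$params$rank),
    paste0("method=", result$method),
    paste0("matrix_format=", matrix_format),
    paste0("tree_format=", tree_format),
    if (!is.null(result$params$scope))
      paste0("scope=", result$params$scope$rank, ":",
             result$params$scope$taxon),
    if (!is.null(result$params$explicit_list))
      paste0("explicit_list=", paste(result$params$explicit_list,
                                     collapse = ",")),
    paste0(names(unclass(th)), "=", vapply(unclass(th), as.character,
                                           character(1))),
    paste0(names(unclass(opts)), "=", vapply(unclass(opts), as.character,
                                             character(1))))
  wr(paste0(paste(par_lines, collapse = "\n"), "\n"), "params.txt")
  invisible(paths)
}
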