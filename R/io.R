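# Readers, writers and validation for the on-disk formats shared by all
# stages. The in-memory convention throughout the package is a samples x OTUs
# numeric matrix with unique dimnames; on disk the classic QIIME layout
# (OTUs as rows, samples as columns) is used.

#' Validate a sample-by-OTU count table
#'
#' Checks that `x` is a numeric matrix of non-negative integers with unique
#' sample and OTU identifiers, and drops samples whose row sum is zero
#' (with a warning).
#'
#' @param x numeric matrix, samples in rows, OTUs in columns, with dimnames.
#' @return the validated matrix (possibly with zero-sum samples removed).
#' @export
validate_count_table <- function(x) {
  if (!is.matrix(x) || !is.numeric(x))
    stop("count table must be a numeric matrix (samples x OTUs)")
  if (is.null(rownames(x)) || is.null(colnames(x)))
    stop("count table must have sample and OTU identifiers as dimnames")
  if (anyDuplicated(rownames(x)))
    stop("duplicate sample identifiers: ",
         paste(unique(rownames(x)[duplicated(rownames(x))]), collapse = ", "))
  if (anyDuplicated(colnames(x)))
    stop("duplicate OTU identifiers: ",
         paste(unique(colnames(x)[duplicated(colnames(x))]), collapse = ", "))
  if (anyNA(x))
    stop("count table contains missing values")
  if (any(x < 0)) {
    bad <- which(x < 0, arr.ind = TRUE)[1, ]
    stop(sprintf("negative count at sample '%s', OTU '%s'",
                 rownames(x)[bad[1]], colnames(x)[bad[2]]))
  }
  if (any(abs(x - round(x)) > 1e-8)) {
    bad <- which(abs(x - round(x)) > 1e-8, arr.ind = TRUE)[1, ]
    stop(sprintf("non-integer count at sample '%s', OTU '%s'",
                 rownames(x)[bad[1]], colnames(x)[bad[2]]))
  }
  x <- round(x)
  rs <- rowSums(x)
  if (any(rs == 0)) {
    warning("dropping ", sum(rs == 0), " sample(s) with zero total counts: ",
            paste(rownames(x)[rs == 0], collapse = ", "))
    x <- x[rs > 0, , drop = FALSE]
  }
  if (nrow(x) == 0) stop("no samples left after validation")
  x
}

#' Read a sample-by-OTU count table
#'
#' Reads either a tab-delimited table in the classic QIIME orientation
#' (OTUs as rows, first column the OTU identifier, samples as columns;
#' lines starting with `#` other than the header are ignored) or a BIOM
#' v1 (JSON) / v2 (HDF5) file. The returned matrix is transposed to the
#' in-memory convention, samples x OTUs, and validated with
#' [validate_count_table()].
#'
#' @param path file path.
#' @param format `"auto"` (by extension), `"tsv"` or `"biom"`.
#' @return samples x OTUs integer matrix.
#' @export
read_count_table <- function(path, format = c("auto", "tsv", "biom")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto")
    format <- if (grepl("\\.biom$", path, ignore.case = TRUE)) "biom" else "tsv"
  if (format == "biom") {
    b <- biomformat::read_biom(path)
    m <- as(biomformat::biom_data(b), "matrix")  # OTUs x samples
    return(validate_count_table(t(m)))
  }
  lines <- readLines(path)
  is_comment <- grepl("^#", lines)
  header_idx <- which(is_comment & grepl("^#OTU", lines, ignore.case = TRUE))
  if (length(header_idx) > 0) {
    # classic QIIME header line "#OTU ID\t..." doubles as the header
    lines[header_idx[1]] <- sub("^#", "", lines[header_idx[1]])
    keep <- sort(unique(c(header_idx[1], which(!is_comment))))
  } else {
    keep <- which(!is_comment)
  }
  if (length(keep) < 2) stop("malformed count table: no data rows")
  df <- utils::read.delim(text = paste(lines[keep], collapse = "\n"),
                          check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2) stop("malformed count table header (need OTU id column plus samples)")
  ids <- as.character(df[[1]])
  non_num <- !vapply(df[-1], is.numeric, logical(1))
  if (any(non_num))
    stop("non-numeric count value(s) in column(s): ",
         paste(names(df)[-1][non_num], collapse = ", "))
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- ids
  validate_count_table(t(m))
}

#' Write a count table to TSV (OTUs as rows)
#'
#' @param table samples x OTUs matrix.
#' @param path output path.
#' @export
write_count_table <- function(table, path) {
  m <- t(table)
  df <- data.frame(`#OTU ID` = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a rooted phylogeny from a Newick file
#'
#' Unrooted trees are midpoint-rooted with a warning; missing branch lengths
#' are set to zero with a warning; negative branch lengths are an error.
#'
#' @param path Newick file.
#' @return an `ape::phylo` object, rooted, with non-negative branch lengths.
#' @export
read_tree <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  tree <- tryCatch(suppressWarnings(ape::read.tree(path)),
                   error = function(e) NULL)
  if (is.null(tree)) stop("unparseable Newick file: ", path)
  prepare_tree(tree)
}

#' Validate and normalize a phylogeny for use by the package
#'
#' @param tree an `ape::phylo` object.
#' @return rooted tree with non-negative branch lengths.
#' @export
prepare_tree <- function(tree) {
  if (!inherits(tree, "phylo")) stop("not a phylo object")
  if (is.null(tree$edge.length)) {
    warning("tree has no branch lengths; setting all to 0")
    tree$edge.length <- rep(0, nrow(tree$edge))
  }
  if (anyNA(tree$edge.length)) {
    warning("tree has ", sum(is.na(tree$edge.length)),
            " missing branch length(s); setting to 0")
    tree$edge.length[is.na(tree$edge.length)] <- 0
  }
  if (any(tree$edge.length < 0)) stop("tree has negative branch lengths")
  if (!ape::is.rooted(tree)) {
    warning("tree is unrooted; rooting at midpoint")
    tree <- phangorn::midpoint(tree)
  }
  if (anyDuplicated(tree$tip.label)) stop("duplicate tip labels in tree")
  tree
}

#' Read a taxonomy table
#'
#' Expects a TSV with the OTU identifier in the first column and a
#' semicolon-delimited ranked lineage (`k__...; p__...; ...; g__Genus`)
#' in the second. Rank prefixes (`k__` etc.) are stripped; missing ranks
#' are `NA`.
#'
#' @param path TSV file.
#' @return data.frame with rownames = OTU ids and columns
#'   `domain, phylum, class, order, family, genus` (plus `species` if given).
#' @export
read_taxonomy <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.delim(path, header = TRUE, comment.char = "#",
                          stringsAsFactors = FALSE, check.names = FALSE)
  if (ncol(df) < 2) stop("taxonomy TSV needs otu_id and lineage columns")
  ids <- as.character(df[[1]])
  if (anyDuplicated(ids)) stop("duplicate OTU ids in taxonomy")
  ranks <- c("domain", "phylum", "class", "order", "family", "genus", "species")
  parts <- strsplit(as.character(df[[2]]), ";")
  out <- matrix(NA_character_, nrow = length(ids), ncol = length(ranks),
                dimnames = list(ids, ranks))
  for (i in seq_along(parts)) {
    p <- trimws(parts[[i]])
    p <- sub("^[a-zA-Z]__", "", p)
    p[p == ""] <- NA_character_
    n <- min(length(p), length(ranks))
    out[i, seq_len(n)] <- p[seq_len(n)]
  }
  as.data.frame(out, stringsAsFactors = FALSE)
}

#' Read sample metadata
#'
#' TSV with columns `sample_id`, `time_point`, `group`. Time points are
#' ordered by first appearance in the file.
#'
#' @param path TSV file.
#' @return data.frame with rownames = sample ids, `time_point` an ordered
#'   factor, `group` character, and a convenience `group_time` label.
#' @export
read_metadata <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.delim(path, header = TRUE, comment.char = "#",
                          stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("sample_id", "time_point", "group")
  if (!all(need %in% names(df)))
    stop("metadata TSV must have columns: ", paste(need, collapse = ", "))
  if (anyDuplicated(df$sample_id)) stop("duplicate sample ids in metadata")
  df$time_point <- factor(df$time_point, levels = unique(df$time_point),
                          ordered = TRUE)
  rownames(df) <- df$sample_id
  df$group_time <- paste(df$group, df$time_point, sep = "_")
  df
}

#' Read a genome function copy-number table
#'
#' TSV with OTU identifiers in the first column and function identifiers
#' (e.g. KO ids) as the remaining column headers; cells are non-negative
#' copy numbers.
#'
#' @param path TSV file.
#' @return OTUs x functions numeric matrix.
#' @export
read_functions <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.delim(path, header = TRUE, comment.char = "",
                          stringsAsFactors = FALSE, check.names = FALSE)
  ids <- as.character(df[[1]])
  if (anyDuplicated(ids)) stop("duplicate OTU ids in function table")
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  if (anyNA(m) || any(m < 0)) stop("function copy numbers must be non-negative numbers")
  rownames(m) <- ids
  m
}

#' Restrict all inputs to a common OTU set
#'
#' The core OTU set is the intersection of the count table and (when given)
#' the tree tips; taxonomy and function tables are subset to it. A function
#' table covering fewer OTUs restricts only the robustness stage: the bundle
#' records the functional sub-set separately and warns. Dropped OTU counts
#' per input are reported. Applying [align_inputs()] twice is a no-op.
#'
#' @param table samples x OTUs count matrix.
#' @param tree optional `phylo`.
#' @param tax optional taxonomy data.frame (see [read_taxonomy()]) or a
#'   named character vector of genus assignments.
#' @param funcs optional OTUs x functions matrix.
#' @return list with elements `table`, `tree`, `tax`, `funcs`, `dropped`
#'   (named counts) of class `assemblage_bundle`.
#' @export
align_inputs <- function(table, tree = NULL, tax = NULL, funcs = NULL) {
  table <- validate_count_table(table)
  core <- colnames(table)
  dropped <- c(table = 0L)
  if (!is.null(tree)) {
    tree <- prepare_tree(tree)
    common <- intersect(core, tree$tip.label)
    if (length(common) == 0) stop("no OTUs shared between count table and tree")
    dropped["table"] <- length(core) - length(common)
    dropped["tree"] <- length(tree$tip.label) - length(common)
    if (dropped["tree"] > 0 || dropped["table"] > 0)
      message("align_inputs: pruned ", dropped["tree"], " tree tip(s), dropped ",
              dropped["table"], " table OTU(s) absent from the tree")
    core <- common
    table <- table[, core, drop = FALSE]
    tree <- ape::keep.tip(tree, core)
  }
  if (!is.null(tax)) {
    if (is.data.frame(tax)) {
      dropped["tax"] <- sum(!(core %in% rownames(tax)))
      tax <- tax[rownames(tax) %in% core, , drop = FALSE]
    } else {
      dropped["tax"] <- sum(!(core %in% names(tax)))
      tax <- tax[names(tax) %in% core]
    }
  }
  if (!is.null(funcs)) {
    common_f <- intersect(core, rownames(funcs))
    if (length(common_f) == 0) stop("no OTUs shared between count table and function table")
    dropped["funcs"] <- length(core) - length(common_f)
    if (dropped["funcs"] > 0)
      warning("function table covers ", length(common_f), " of ", length(core),
              " OTUs; robustness analyses are restricted to that subset")
    funcs <- funcs[common_f, , drop = FALSE]
  }
  rs <- rowSums(table)
  if (any(rs == 0)) {
    warning("dropping ", sum(rs == 0), " sample(s) empty after OTU alignment")
    table <- table[rs > 0, , drop = FALSE]
  }
  structure(list(table = table, tree = tree, tax = tax, funcs = funcs,
                 dropped = dropped),
            class = "assemblage_bundle")
}

#' Convert counts to relative abundances
#'
#' @param table samples x OTUs matrix with positive row sums.
#' @return matrix of the same shape with rows summing to 1.
#' @export
to_relative <- function(table) {
  rs <- rowSums(table)
  if (any(rs <= 0)) stop("cannot normalize sample(s) with zero total: ",
                         paste(rownames(table)[rs <= 0], collapse = ", "))
  sweep(table, 1, rs, "/")
}
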