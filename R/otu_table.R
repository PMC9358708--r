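#' Construct an OTU table
#'
#' An `otu_table` is a numeric taxa x samples matrix with unique row (taxon)
#' and column (sample) identifiers and a declared unit: `"counts"` (integer
#' reads) or `"proportions"` (each sample column sums to 1).
#'
#' @param x numeric matrix, taxa as rows, samples as columns, with dimnames.
#' @param unit `"counts"` or `"proportions"`. If missing, inferred: a matrix
#'   of whole numbers is treated as counts, anything else as proportions.
#' @return An `otu_table`: the validated matrix with class and `unit`
#'   attributes.
#' @export
otu_table <- function(x, unit = NULL) {
  if (!is.matrix(x) || !is.numeric(x)) {
    stop("`x` must be a numeric matrix (taxa x samples)", call. = FALSE)
  }
  if (is.null(rownames(x)) || is.null(colnames(x))) {
    stop("`x` must have taxon rownames and sample colnames", call. = FALSE)
  }
  dup_t <- unique(rownames(x)[duplicated(rownames(x))])
  dup_s <- unique(colnames(x)[duplicated(colnames(x))])
  if (length(dup_t)) {
    stop("duplicate taxon identifiers: ", paste(dup_t, collapse = ", "),
         call. = FALSE)
  }
  if (length(dup_s)) {
    stop("duplicate sample identifiers: ", paste(dup_s, collapse = ", "),
         call. = FALSE)
  }
  if (anyNA(x) || any(x < 0)) {
    bad <- which(is.na(x) | x < 0, arr.ind = TRUE)[1, , drop = TRUE]
    stop(sprintf("negative or missing abundance at taxon '%s', sample '%s'",
                 rownames(x)[bad[1]], colnames(x)[bad[2]]), call. = FALSE)
  }
  is_int <- all(abs(x - round(x)) < 1e-9)
  if (is.null(unit)) unit <- if (is_int) "counts" else "proportions"
  unit <- match.arg(unit, c("counts", "proportions"))
  if (unit == "counts") {
    if (!is_int) stop("unit \"counts\" requires integer values", call. = FALSE)
    x <- round(x)
  } else {
    cs <- colSums(x)
    if (any(cs == 0)) {
      stop("empty sample column(s) not allowed for proportions: ",
           paste(colnames(x)[cs == 0], collapse = ", "), call. = FALSE)
    }
    if (any(abs(cs - 1) > 1e-9)) {
      stop("proportion columns must sum to 1 (tolerance 1e-9); offending: ",
           paste(colnames(x)[abs(cs - 1) > 1e-9], collapse = ", "),
           call. = FALSE)
    }
  }
  structure(x, class = c("otu_table", "matrix", "array"), unit = unit)
}

#' @export
print.otu_table <- function(x, ...) {
  cat(sprintf("otu_table: %d taxa x %d samples (%s)\n",
              nrow(x), ncol(x), attr(x, "unit")))
  invisible(x)
}

#' Unit of an OTU table
#' @param x an `otu_table`.
#' @return `"counts"` or `"proportions"`.
#' @export
otu_unit <- function(x) attr(x, "unit")

# rebuild the class/unit attributes after a plain-matrix operation
as_otu <- function(x, unit) structure(as.matrix(x),
                                      class = c("otu_table", "matrix", "array"),
                                      unit = unit)

#' Read an OTU table from tab-separated text
#'
#' Expects one header row of identifiers and a numeric body. Leading lines
#' starting with `#` are ignored, except a `#OTU ID`-style header whose `#`
#' is stripped (the common QIIME convention).
#'
#' @param path path to a TSV file.
#' @param orientation which axis of the file holds taxa: `"taxa_rows"`
#'   (default) or `"samples_rows"`.
#' @return An [otu_table()] (taxa x samples) with unit inferred from the
#'   values; row and column order of the file is preserved.
#' @export
read_otu_table <- function(path, orientation = c("taxa_rows", "samples_rows")) {
  orientation <- match.arg(orientation)
  lines <- readLines(path)
  is_comment <- startsWith(lines, "#")
  first_data <- match(FALSE, is_comment)
  if (is.na(first_data)) stop("no data lines in ", path, call. = FALSE)
  keep <- lines[first_data:length(lines)]
  # a comment line directly above the body is the header if it looks like one
  if (first_data > 1) {
    hdr <- lines[first_data - 1]
    if (grepl("^#\\s*OTU", hdr, ignore.case = TRUE) || first_data == 1) {
      keep <- c(sub("^#", "", hdr), keep)
    } else if (length(strsplit(hdr, "\t")[[1]]) ==
               length(strsplit(keep[1], "\t")[[1]])) {
      keep <- c(sub("^#", "", hdr), keep)
    }
  }
  df <- utils::read.table(text = keep, sep = "\t", header = TRUE,
                          check.names = FALSE, comment.char = "",
                          colClasses = "character")
  ids <- df[[1]]
  body <- df[, -1, drop = FALSE]
  m <- suppressWarnings(matrix(as.numeric(as.matrix(body)),
                               nrow = nrow(body),
                               dimnames = list(ids, colnames(body))))
  if (anyNA(m)) {
    bad <- which(is.na(m), arr.ind = TRUE)[1, ]
    stop(sprintf("non-numeric cell at row '%s', column '%s' in %s",
                 ids[bad[1]], colnames(body)[bad[2]], path), call. = FALSE)
  }
  if (orientation == "samples_rows") m <- t(m)
  otu_table(m)
}

#' Write an OTU table as tab-separated text
#'
#' @param table an [otu_table()].
#' @param path output path.
#' @param id_header header cell for the taxon-identifier column.
#' @return `path`, invisibly.
#' @export
write_otu_table <- function(table, path, id_header = "taxon_id") {
  df <- data.frame(id = rownames(table), as.data.frame(unclass(table)),
                   check.names = FALSE)
  colnames(df)[1] <- id_header
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read per-sample environmental metadata
#'
#' Tab-separated text with the sample identifier in the first column and
#' numeric variables in the rest (blank cells are missing). The stoichiometric
#' ratios `C:N` (= SOC/TN), `C:P` (= SOC/TP) and `N:P` (= TN/TP) are derived
#' when SOC/TN/TP are present and the ratio column is not already supplied;
#' division by zero yields a missing value with a warning. Supplied ratio
#' columns take precedence and are never recomputed.
#'
#' @param path path to the TSV file.
#' @return A data frame with `sample_id` plus numeric variables; sample ids
#'   also stored as row names.
#' @export
read_metadata <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                          comment.char = "#", colClasses = "character",
                          na.strings = c("", "NA"))
  sample_id <- df[[1]]
  if (anyDuplicated(sample_id)) {
    stop("duplicate sample identifiers: ",
         paste(unique(sample_id[duplicated(sample_id)]), collapse = ", "),
         call. = FALSE)
  }
  vars <- df[, -1, drop = FALSE]
  for (j in seq_along(vars)) {
    raw <- vars[[j]]
    num <- suppressWarnings(as.numeric(raw))
    bad <- which(!is.na(raw) & is.na(num))
    if (length(bad)) {
      stop(sprintf("non-numeric cell at sample '%s', column '%s' in %s",
                   sample_id[bad[1]], colnames(vars)[j], path), call. = FALSE)
    }
    vars[[j]] <- num
  }
  ratios <- list("C:N" = c("SOC", "TN"), "C:P" = c("SOC", "TP"),
                 "N:P" = c("TN", "TP"))
  for (r in names(ratios)) {
    parts <- ratios[[r]]
    if (!r %in% colnames(vars) && all(parts %in% colnames(vars))) {
      num <- vars[[parts[1]]]
      den <- vars[[parts[2]]]
      q <- num / den
      zero <- !is.na(den) & den == 0
      if (any(zero)) {
        warning(sprintf("%s undefined (zero %s) for sample(s): %s",
                        r, parts[2],
                        paste(sample_id[zero], collapse = ", ")),
                call. = FALSE)
        q[zero] <- NA_real_
      }
      vars[[r]] <- q
    }
  }
  out <- data.frame(sample_id = sample_id, vars, check.names = FALSE)
  rownames(out) <- sample_id
  out
}

#' Read a phylogenetic tree from newick text
#'
#' Wraps [ape::read.tree()] with validation: tip labels must be unique, and
#' missing branch lengths are defaulted to 0 with a warning.
#'
#' @param path path to a newick file.
#' @return An [ape::read.tree()] `phylo` object.
#' @export
read_tree <- function(path) {
  tree <- tryCatch(ape::read.tree(path),
                   error = function(e) stop("unparsable newick in ", path,
                                            ": ", conditionMessage(e),
                                            call. = FALSE))
  if (is.null(tree)) stop("unparsable newick in ", path, call. = FALSE)
  dup <- unique(tree$tip.label[duplicated(tree$tip.label)])
  if (length(dup)) {
    stop("duplicate tip labels: ", paste(dup, collapse = ", "), call. = FALSE)
  }
  if (is.null(tree$edge.length)) {
    warning("tree has no branch lengths; defaulting all to 0", call. = FALSE)
    tree$edge.length <- rep(0, nrow(tree$edge))
  } else if (anyNA(tree$edge.length)) {
    warning("missing branch lengths defaulted to 0", call. = FALSE)
    tree$edge.length[is.na(tree$edge.length)] <- 0
  }
  tree
}

#' Rarefy a count table to a common depth
#'
#' Each sample is subsampled uniformly without replacement (hypergeometric)
#' down to exactly `depth` reads. Samples with fewer than `depth` total reads
#' are dropped with a warning. Taxa left with all-zero rows are retained
#' unless `drop_empty = TRUE`.
#'
#' @param table an [otu_table()] with unit `"counts"`.
#' @param depth target reads per sample (positive integer).
#' @param seed integer seed; the result is deterministic given
#'   (table, depth, seed).
#' @param drop_empty drop taxa whose counts are all zero after rarefaction.
#' @return A rarefied count [otu_table()].
#' @export
rarefy_table <- function(table, depth, seed = 1L, drop_empty = FALSE) {
  stopifnot(inherits(table, "otu_table"))
  if (otu_unit(table) != "counts") {
    stop("rarefaction requires a count table", call. = FALSE)
  }
  if (length(depth) != 1 || is.na(depth) || depth <= 0) {
    stop("`depth` must be a positive integer", call. = FALSE)
  }
  depth <- as.integer(round(depth))
  totals <- colSums(table)
  shallow <- totals < depth
  if (all(shallow)) {
    stop("all samples have fewer than ", depth, " reads", call. = FALSE)
  }
  if (any(shallow)) {
    warning("dropping sample(s) below depth ", depth, ": ",
            paste(colnames(table)[shallow], collapse = ", "), call. = FALSE)
  }
  kept <- unclass(table)[, !shallow, drop = FALSE]
  set.seed(as.integer(seed))
  # vegan heuristically warns when counts "look" unobserved; irrelevant here
  rar <- withCallingHandlers(
    t(vegan::rrarefy(t(kept), sample = depth)),
    warning = function(w) {
      if (grepl("observed counts", conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    })
  if (drop_empty) rar <- rar[rowSums(rar) > 0, , drop = FALSE]
  as_otu(rar, "counts")
}

#' Convert an OTU table to relative abundances
#'
#' Divides each sample column by its total. A proportions table is returned
#' unchanged (idempotent).
#'
#' @param table an [otu_table()].
#' @return An [otu_table()] with unit `"proportions"`.
#' @export
to_relative_abundance <- function(table) {
  stopifnot(inherits(table, "otu_table"))
  if (otu_unit(table) == "proportions") return(table)
  cs <- colSums(table)
  if (any(cs == 0)) {
    stop("all-zero sample column(s): ",
         paste(colnames(table)[cs == 0], collapse = ", "), call. = FALSE)
  }
  as_otu(sweep(unclass(table), 2, cs, "/"), "proportions")
}
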