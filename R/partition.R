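#' Abundance thresholds for the abundant/rare partition
#'
#' Defaults follow the common abundant/rare biosphere convention: abundant at
#' a relative abundance of at least 0.1% (inclusive), rare below 0.01%
#' (exclusive). Everything in between is "intermediate".
#'
#' @param abundant_min minimum proportion for "abundant" (default 0.001).
#' @param rare_max exclusive upper proportion for "rare" (default 0.0001).
#' @return A list with class `abundance_thresholds`.
#' @export
abundance_thresholds <- function(abundant_min = 0.001, rare_max = 0.0001) {
  if (!(rare_max > 0 && rare_max < abundant_min && abundant_min < 1)) {
    stop("need 0 < rare_max < abundant_min < 1", call. = FALSE)
  }
  structure(list(abundant_min = abundant_min, rare_max = rare_max),
            class = "abundance_thresholds")
}

#' Classify taxa at the regional (metacommunity) level
#'
#' A taxon's mean relative abundance across ALL samples (zeros included) is
#' compared to the thresholds: `>= abundant_min` is abundant, `< rare_max` is
#' rare, anything between is intermediate.
#'
#' @param table an [otu_table()] (counts or proportions); classification is
#'   invariant to per-sample rescaling.
#' @param thresholds an [abundance_thresholds()].
#' @return A `taxon_classification` with `level = "regional"` and a named
#'   character vector `labels` (one of abundant/intermediate/rare per taxon).
#' @export
classify_regional <- function(table, thresholds = abundance_thresholds()) {
  stopifnot(inherits(table, "otu_table"))
  if (nrow(table) == 0 || ncol(table) == 0) stop("empty table", call. = FALSE)
  prop <- to_relative_abundance(table)
  mra <- rowMeans(unclass(prop))
  labels <- ifelse(mra >= thresholds$abundant_min, "abundant",
                   ifelse(mra < thresholds$rare_max, "rare", "intermediate"))
  names(labels) <- rownames(table)
  structure(list(level = "regional", labels = labels, mean_abundance = mra,
                 thresholds = thresholds),
            class = "taxon_classification")
}

#' Classify taxa per sample (local level)
#'
#' Per (taxon, sample): proportion `>= abundant_min` is abundant, strictly
#' between 0 and `rare_max` is rare, exactly 0 is absent, otherwise
#' intermediate.
#'
#' @inheritParams classify_regional
#' @return A `taxon_classification` with `level = "local"` and a taxa x
#'   samples character matrix `labels`.
#' @export
classify_local <- function(table, thresholds = abundance_thresholds()) {
  stopifnot(inherits(table, "otu_table"))
  if (nrow(table) == 0 || ncol(table) == 0) stop("empty table", call. = FALSE)
  p <- unclass(to_relative_abundance(table))
  labels <- matrix("intermediate", nrow(p), ncol(p), dimnames = dimnames(p))
  labels[p >= thresholds$abundant_min] <- "abundant"
  labels[p > 0 & p < thresholds$rare_max] <- "rare"
  labels[p == 0] <- "absent"
  structure(list(level = "local", labels = labels, thresholds = thresholds),
            class = "taxon_classification")
}

#' @export
print.taxon_classification <- function(x, ...) {
  cat(sprintf("taxon_classification (%s level)\n", x$level))
  print(table(x$labels))
  invisible(x)
}

#' Extract a subcommunity table
#'
#' Restricts the table to the taxa carrying a regional category label. The
#' sample set is unchanged and counts are NOT renormalized; downstream
#' distance computations renormalize within the subcommunity.
#'
#' @param table an [otu_table()].
#' @param classification a regional [classify_regional()] result.
#' @param category `"abundant"`, `"rare"` or `"intermediate"`.
#' @return An [otu_table()] with the selected taxa only.
#' @export
subset_subcommunity <- function(table, classification,
                                category = c("abundant", "rare",
                                             "intermediate")) {
  stopifnot(inherits(table, "otu_table"),
            inherits(classification, "taxon_classification"))
  if (classification$level != "regional") {
    stop("subcommunities are defined by the regional classification",
         call. = FALSE)
  }
  category <- match.arg(category)
  taxa <- names(classification$labels)[classification$labels == category]
  taxa <- intersect(rownames(table), taxa)
  if (length(taxa) == 0) {
    stop("no taxa in category \"", category, "\"", call. = FALSE)
  }
  as_otu(unclass(table)[taxa, , drop = FALSE], otu_unit(table))
}

#' Per-sample richness and abundance summary by category
#'
#' For each sample and local category: OTU richness (number of taxa with that
#' label), the category's share of observed richness, and the summed relative
#' abundance. Across-sample means are attached.
#'
#' @param table the [otu_table()] the local classification was computed from.
#' @param local a local [classify_local()] result.
#' @return A list with class `category_summary`: `per_sample` (long data
#'   frame: sample_id, category, richness, richness_share, abundance) and
#'   `means` (across-sample means per category).
#' @export
category_summary <- function(table, local) {
  stopifnot(inherits(table, "otu_table"),
            inherits(local, "taxon_classification"))
  if (local$level != "local") stop("need a local classification", call. = FALSE)
  if (!identical(dimnames(unclass(table)), dimnames(local$labels))) {
    stop("classification does not match table dimensions", call. = FALSE)
  }
  p <- unclass(to_relative_abundance(table))
  cats <- c("abundant", "intermediate", "rare")
  rows <- list()
  for (s in colnames(p)) {
    lab <- local$labels[, s]
    observed <- sum(lab != "absent")
    for (cc in cats) {
      in_cat <- lab == cc
      rows[[length(rows) + 1L]] <- data.frame(
        sample_id = s, category = cc,
        richness = sum(in_cat),
        richness_share = if (observed > 0) sum(in_cat) / observed else NA_real_,
        abundance = sum(p[in_cat, s]),
        stringsAsFactors = FALSE)
    }
  }
  per_sample <- do.call(rbind, rows)
  means <- stats::aggregate(
    per_sample[c("richness", "richness_share", "abundance")],
    by = list(category = per_sample$category), FUN = mean)
  structure(list(per_sample = per_sample, means = means),
            class = "category_summary")
}

#' Export a classification as tab-separated text
#'
#' Regional classifications produce `taxon_id`, `category` columns; local
#' classifications produce `taxon_id`, `sample_id`, `category`.
#'
#' @param classification a `taxon_classification`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_classification <- function(classification, path) {
  stopifnot(inherits(classification, "taxon_classification"))
  if (classification$level == "regional") {
    df <- data.frame(taxon_id = names(classification$labels),
                     category = unname(classification$labels))
  } else {
    lab <- classification$labels
    df <- data.frame(taxon_id = rep(rownames(lab), times = ncol(lab)),
                     sample_id = rep(colnames(lab), each = nrow(lab)),
                     category = as.vector(lab))
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
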