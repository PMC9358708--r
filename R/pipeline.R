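#' Configuration for the full assembly analysis
#'
#' Inputs may be in-memory objects ([otu_table()], data frame, `phylo` /
#' distance matrix) or file paths to the corresponding TSV / newick formats.
#'
#' @param otu OTU count table or path.
#' @param metadata sample metadata data frame or path.
#' @param tree phylogeny (`phylo` or newick path); alternatively
#'   `taxon_dist`, a taxon distance matrix (or its TSV path) from which a
#'   neighbor-joining tree is built.
#' @param taxon_dist see `tree`.
#' @param depth rarefaction depth; `NULL` skips rarefaction.
#' @param rarefy_seed seed for the rarefaction subsample.
#' @param thresholds an [abundance_thresholds()].
#' @param null_cfg a [null_model_config()] (carries the master seed, 999
#'   nulls, the betaNTI/RC thresholds and the sign convention).
#' @param weighted abundance-weight betaMNTD.
#' @param mantel_method `"pearson"` or `"spearman"`.
#' @param mantel_perm Mantel permutations (default 999).
#' @param env_vars metadata variables for divergence/Mantel panels
#'   (default: all numeric metadata columns).
#' @param out_dir output directory; `NULL` keeps results in memory only.
#' @return A list with class `pipeline_config`.
#' @export
pipeline_config <- function(otu, metadata, tree = NULL, taxon_dist = NULL,
                            depth = NULL, rarefy_seed = 1L,
                            thresholds = abundance_thresholds(),
                            null_cfg = null_model_config(),
                            weighted = TRUE,
                            mantel_method = "pearson", mantel_perm = 999L,
                            env_vars = NULL, out_dir = NULL) {
  if (is.null(tree) && is.null(taxon_dist)) {
    stop("provide `tree` or `taxon_dist`", call. = FALSE)
  }
  for (pth in Filter(is.character, list(otu, metadata, tree, taxon_dist))) {
    if (!file.exists(pth)) stop("input file not found: ", pth, call. = FALSE)
  }
  structure(list(otu = otu, metadata = metadata, tree = tree,
                 taxon_dist = taxon_dist, depth = depth,
                 rarefy_seed = as.integer(rarefy_seed),
                 thresholds = thresholds, null_cfg = null_cfg,
                 weighted = weighted, mantel_method = mantel_method,
                 mantel_perm = as.integer(mantel_perm),
                 env_vars = env_vars, out_dir = out_dir),
            class = "pipeline_config")
}

#' Run the full abundant/rare assembly analysis
#'
#' Stages: (optional) rarefaction; regional and local abundance
#' classification; per-category richness/abundance summaries and Spearman
#' correlations against the environment; for each of the abundant, rare and
#' all-taxa tables: Bray-Curtis, betaMNTD, betaNTI, RC-Bray and the five-way
#' process classification; rank-sum comparisons of the abundant vs rare
#' Bray-Curtis and betaMNTD pair vectors; and Mantel tests of every
#' beta-diversity and betaNTI matrix against every environmental divergence.
#' When `cfg$out_dir` is set, every table/matrix is written there along with
#' `summary.json` (process fractions and deterministic/stochastic shares;
#' no timestamps, so reruns are byte-identical) and `run.log`.
#'
#' @param cfg a [pipeline_config()].
#' @return A list with class `pipeline_result`: `table` (analyzed
#'   [otu_table()]), `classification` (regional, local), `summary`
#'   ([category_summary()]), `spearman`, per-subcommunity `subcommunities`
#'   (each with `bray`, `bmntd`, `bnti`, `rc`, `assembly`), `rank_sum`,
#'   `mantel` (long data frame), `process_summary`.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "pipeline_config"))
  log_lines <- c(sprintf("ecoassembly %s",
                         as.character(utils::packageVersion("ecoassembly"))),
                 sprintf("master seed: %d", cfg$null_cfg$seed),
                 sprintf("rarefaction seed: %d", cfg$rarefy_seed))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
  }
  otu <- stage("read_otu", {
    if (is.character(cfg$otu)) read_otu_table(cfg$otu) else cfg$otu
  })
  metadata <- stage("read_metadata", {
    if (is.character(cfg$metadata)) read_metadata(cfg$metadata)
    else cfg$metadata
  })
  patristic <- stage("phylogeny", {
    if (!is.null(cfg$tree)) {
      tr <- if (is.character(cfg$tree)) read_tree(cfg$tree) else cfg$tree
      patristic_distances(tr)
    } else {
      td <- if (is.character(cfg$taxon_dist)) read_dist_tsv(cfg$taxon_dist)
            else cfg$taxon_dist
      patristic_distances(nj_tree(td))
    }
  })
  if (!is.null(cfg$depth)) {
    otu <- stage("rarefy", rarefy_table(otu, cfg$depth,
                                        seed = cfg$rarefy_seed))
    log_lines <- c(log_lines, sprintf("rarefied to depth %d, %d samples kept",
                                      cfg$depth, ncol(otu)))
  }
  metadata <- metadata[metadata$sample_id %in% colnames(otu), , drop = FALSE]
  regional <- stage("classify_regional", classify_regional(otu,
                                                           cfg$thresholds))
  local <- stage("classify_local", classify_local(otu, cfg$thresholds))
  summ <- stage("category_summary", category_summary(otu, local))
  env_vars <- cfg$env_vars
  if (is.null(env_vars)) {
    env_vars <- setdiff(colnames(metadata)[vapply(metadata, is.numeric,
                                                  logical(1))], "sample_id")
  }
  spearman <- stage("spearman",
                    spearman_correlations(summ, metadata,
                                          variables = env_vars))
  subtabs <- list(
    abundant = stage("subset_abundant",
                     subset_subcommunity(otu, regional, "abundant")),
    rare = stage("subset_rare", subset_subcommunity(otu, regional, "rare")),
    all = otu)
  sub <- lapply(names(subtabs), function(nm) {
    tab <- subtabs[[nm]]
    bray <- stage(paste0("bray_", nm), bray_curtis_matrix(tab))
    bmntd <- stage(paste0("bmntd_", nm),
                   beta_mntd_matrix(tab, patristic, weighted = cfg$weighted))
    bnti <- stage(paste0("bnti_", nm),
                  bnti_matrix(tab, patristic, cfg$null_cfg,
                              weighted = cfg$weighted))
    rc <- stage(paste0("rc_", nm), rc_bray_matrix(tab, cfg$null_cfg))
    asm <- stage(paste0("classify_", nm),
                 classify_assembly(bnti, rc, cfg$null_cfg))
    list(table = tab, bray = bray, bmntd = bmntd, bnti = bnti, rc = rc,
         assembly = asm)
  })
  names(sub) <- names(subtabs)
  rank_sum <- stage("rank_sum", list(
    bray = rank_sum_test(lower_vec(sub$abundant$bray),
                         lower_vec(sub$rare$bray)),
    bmntd = rank_sum_test(lower_vec(sub$abundant$bmntd),
                          lower_vec(sub$rare$bmntd))))
  mantel_rows <- list()
  for (v in env_vars) {
    ed <- tryCatch(env_distance(metadata, v), error = function(e) NULL)
    if (is.null(ed) || isTRUE(attr(ed, "constant"))) next
    for (nm in names(sub)) {
      for (metric in c("bray", "bmntd", "bnti")) {
        mat <- if (metric == "bnti") sub[[nm]]$bnti$bnti else sub[[nm]][[metric]]
        if (anyNA(mat)) next   # degenerate betaNTI pairs: Mantel undefined
        shared <- intersect(rownames(mat), rownames(ed))
        if (length(shared) < 4) next
        # constant matrices (e.g. a one-taxon subcommunity) have no Mantel
        if (stats::sd(lower_vec(mat[shared, shared])) == 0) next
        mt <- stage(sprintf("mantel_%s_%s_%s", nm, metric, v),
                    mantel_test(mat[shared, shared], ed[shared, shared],
                                n_perm = cfg$mantel_perm,
                                seed = derive_seed(cfg$null_cfg$seed,
                                                   paste("mantel", nm,
                                                         metric, v)),
                                method = cfg$mantel_method))
        mantel_rows[[length(mantel_rows) + 1L]] <- data.frame(
          subcommunity = nm, metric = metric, variable = v,
          r = mt$r, p = mt$p, n_perm = mt$n_perm, stringsAsFactors = FALSE)
      }
    }
  }
  mantel <- if (length(mantel_rows)) do.call(rbind, mantel_rows) else NULL
  process_summary <- lapply(sub, function(x) {
    c(as.list(x$assembly$fractions),
      deterministic = x$assembly$deterministic,
      stochastic = x$assembly$stochastic,
      n_pairs = x$assembly$n_defined,
      n_degenerate = x$assembly$n_degenerate)
  })
  result <- structure(list(table = otu,
                           classification = list(regional = regional,
                                                 local = local),
                           summary = summ, spearman = spearman,
                           subcommunities = sub, rank_sum = rank_sum,
                           mantel = mantel,
                           process_summary = process_summary,
                           config = cfg),
                      class = "pipeline_result")
  if (!is.null(cfg$out_dir)) {
    write_pipeline_outputs(result, cfg$out_dir, log_lines)
  }
  invisible(result)
}

write_pipeline_outputs <- function(result, out_dir, log_lines) {
  tdir <- file.path(out_dir, "tables")
  mdir <- file.path(out_dir, "matrices")
  dir.create(tdir, recursive = TRUE, showWarnings = FALSE)
  dir.create(mdir, recursive = TRUE, showWarnings = FALSE)
  write_classification(result$classification$regional,
                       file.path(tdir, "classification_regional.tsv"))
  utils::write.table(result$summary$per_sample,
                     file.path(tdir, "category_summary.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(result$spearman,
                     file.path(tdir, "spearman_correlations.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(result$mantel)) {
    utils::write.table(result$mantel, file.path(tdir, "mantel_tests.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  for (nm in names(result$subcommunities)) {
    x <- result$subcommunities[[nm]]
    write_dist_tsv(x$bray, file.path(mdir, paste0("bray_", nm, ".tsv")))
    write_dist_tsv(x$bmntd, file.path(mdir, paste0("bmntd_", nm, ".tsv")))
    utils::write.table(x$assembly$pairs,
                       file.path(tdir, paste0("pairs_", nm, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  jsonlite::write_json(result$process_summary,
                       file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  writeLines(c(log_lines, format(Sys.time(), "finished %Y-%m-%d %H:%M:%S")),
             file.path(out_dir, "run.log"))
  invisible(out_dir)
}
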