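#' Configuration for a full signature-discovery run
#'
#' Exactly one of `synthetic` (a [synthetic_config()]) or `inputs` (paths to
#' a matrix TSV and labels TSV) must be supplied.  Per-stage seeds are
#' derived from `root_seed` and the stage name, so any stage can be re-run
#' standalone and reproduce its in-pipeline output.
#'
#' @param synthetic A [synthetic_config()], or `NULL` to analyze real data.
#' @param inputs `list(matrix = <tsv>, labels = <tsv>)`, or `NULL`.
#' @param boruta A [boruta_params()].
#' @param mcfs A [mcfs_params()].
#' @param classifier A [classifier_params()].
#' @param cutoff Options for [top_ranking_cutoff()]:
#'   `list(n_perm, null_quantile, fixed_k)`.  `n_perm = 0` skips the
#'   permutation null and carries the whole ranked list into IFS.
#' @param ifs `list(max_k, step)`; `max_k = NULL` sweeps the whole
#'   top-ranking list.
#' @param gene_sets Optional path to a GMT file (enrichment is skipped when
#'   `NULL`).
#' @param fdr_threshold Significance level for enrichment FDR.
#' @param root_seed Integer root seed.
#' @param output_dir Directory for stage outputs and the manifest.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(synthetic = NULL, inputs = NULL,
                            boruta = boruta_params(),
                            mcfs = mcfs_params(),
                            classifier = classifier_params(),
                            cutoff = list(n_perm = 10L, null_quantile = 0.95,
                                          fixed_k = NULL),
                            ifs = list(max_k = NULL, step = 1L),
                            gene_sets = NULL,
                            fdr_threshold = 0.05,
                            root_seed = 1L,
                            output_dir = tempfile("sigfunnel_run_")) {
  if (is.null(synthetic) == is.null(inputs))
    stop_invalid("supply exactly one of `synthetic` or `inputs`")
  structure(list(synthetic = synthetic, inputs = inputs, boruta = boruta,
                 mcfs = mcfs, classifier = classifier, cutoff = cutoff,
                 ifs = ifs, gene_sets = gene_sets,
                 fdr_threshold = fdr_threshold,
                 root_seed = as.integer(root_seed), output_dir = output_dir),
            class = "pipeline_config")
}

run_stage <- function(name, verbose, expr) {
  t0 <- proc.time()[["elapsed"]]
  out <- tryCatch(expr, error = function(e)
    stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
         call. = FALSE))
  if (verbose)
    message(sprintf("[%s] done in %.1fs", name,
                    proc.time()[["elapsed"]] - t0))
  out
}

manifest_entry <- function(stage, seed, params, files, counts = NULL) {
  list(stage = stage, seed = seed, params = params,
       outputs = lapply(files, function(f)
         list(file = basename(f), md5 = unname(tools::md5sum(f)))),
       counts = counts)
}

#' Run the full signature-discovery funnel
#'
#' Chains simulate/load -> quantile normalization -> Boruta all-relevant
#' filtering -> MCFS ranking (with a permutation-null top-ranking cutoff) ->
#' IFS signature selection by SVM LOOCV -> optional gene-set enrichment.
#' Every stage writes plain TSV/JSON artifacts under `cfg$output_dir`
#' together with a manifest (stage, parameters, seed, output checksums), so
#' each stage can be re-run standalone from its inputs.
#'
#' If Boruta confirms fewer than 2 genes, or the top-ranking cutoff retains
#' fewer than 2, the downstream stages are skipped and the report records an
#' empty signature.
#'
#' @param cfg A [pipeline_config()].
#' @param verbose Emit per-stage timing messages.
#' @return A `pipeline_report` list: the gene-count funnel
#'   (`n_genes`, `n_confirmed`, `n_top_ranking`, `k_star`), `accuracy`,
#'   `signature`, `confusion`, the enrichment table (or `NULL`), and
#'   `output_dir`.
#' @export
run_pipeline <- function(cfg, verbose = TRUE) {
  stopifnot(inherits(cfg, "pipeline_config"))
  dir.create(cfg$output_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list()
  pth <- function(f) file.path(cfg$output_dir, f)

  # -- data ----------------------------------------------------------------
  dat <- run_stage("data", verbose, {
    if (!is.null(cfg$synthetic)) {
      sc <- cfg$synthetic
      sc$seed <- derive_seed(cfg$root_seed, "simulate")
      ds <- generate_dataset(sc)
      write_dataset(ds, cfg$output_dir)
      list(matrix = ds$matrix, labels = ds$labels,
           truth = ds$truth$informative_genes)
    } else {
      m <- read_expression_matrix(cfg$inputs$matrix)
      lab <- read_labels(cfg$inputs$labels)
      list(matrix = m, labels = assert_labels(lab, m), truth = NULL)
    }
  })
  manifest$data <- manifest_entry(
    "data", derive_seed(cfg$root_seed, "simulate"),
    if (!is.null(cfg$synthetic)) unclass(cfg$synthetic) else cfg$inputs,
    if (!is.null(cfg$synthetic)) pth("matrix.tsv") else character(0),
    counts = list(n_genes = nrow(dat$matrix), n_samples = ncol(dat$matrix)))

  # -- normalize -----------------------------------------------------------
  norm <- run_stage("normalize", verbose, quantile_normalize(dat$matrix))
  write_expression_matrix(norm, pth("normalized.tsv"))
  manifest$normalize <- manifest_entry(
    "normalize", NA, list(), pth("normalized.tsv"),
    counts = list(n_genes = nrow(norm)))

  # -- boruta --------------------------------------------------------------
  bp <- cfg$boruta
  bp$seed <- derive_seed(cfg$root_seed, "boruta")
  bres <- run_stage("boruta", verbose, boruta_run(norm, dat$labels, bp))
  confirmed <- confirmed_features(bres)
  bout <- data.frame(gene_id = names(bres$status),
                     status = as.character(bres$status),
                     mean_importance = rowMeans(bres$importance_history,
                                                na.rm = TRUE))
  write.table(bout, pth("boruta.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  manifest$boruta <- manifest_entry(
    "boruta", bp$seed, unclass(bp), pth("boruta.tsv"),
    counts = list(n_confirmed = length(confirmed)))

  # -- mcfs + cutoff -------------------------------------------------------
  ranked <- NULL
  top_genes <- character(0)
  cutoff_k <- 0L
  if (length(confirmed) >= 2) {
    mp <- cfg$mcfs
    mp$seed <- derive_seed(cfg$root_seed, "mcfs")
    sub <- norm[confirmed, , drop = FALSE]
    ranked <- run_stage("mcfs", verbose, mcfs(sub, dat$labels, mp))
    write.table(as.data.frame(ranked), pth("mcfs_ranking.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    cutoff_k <- run_stage("cutoff", verbose, {
      if (!is.null(cfg$cutoff$fixed_k)) {
        min(as.integer(cfg$cutoff$fixed_k), nrow(ranked))
      } else if (cfg$cutoff$n_perm < 1) {
        nrow(ranked)
      } else {
        as.integer(top_ranking_cutoff(
          ranked, sub, dat$labels, attr(ranked, "params"),
          n_perm = cfg$cutoff$n_perm,
          null_quantile = cfg$cutoff$null_quantile))
      }
    })
    top_genes <- ranked$gene_id[seq_len(cutoff_k)]
    manifest$mcfs <- manifest_entry(
      "mcfs", mp$seed, unclass(attr(ranked, "params")),
      pth("mcfs_ranking.tsv"),
      counts = list(n_ranked = nrow(ranked), n_top_ranking = cutoff_k))
  }

  # -- ifs -----------------------------------------------------------------
  sig <- list(k_star = 0L, accuracy = NA_real_, genes = character(0),
              confusion = NULL)
  if (length(top_genes) >= 2) {
    top_ranked <- ranked[seq_along(top_genes), , drop = FALSE]
    attr(top_ranked, "N") <- length(top_genes)
    class(top_ranked) <- c("ranked_features", "data.frame")
    max_k <- min(cfg$ifs$max_k %||% length(top_genes), length(top_genes))
    curve <- run_stage("ifs", verbose,
                       ifs_curve(top_ranked, norm, dat$labels,
                                 cfg$classifier, max_k = max_k,
                                 step = cfg$ifs$step))
    sig <- select_signature(curve, top_ranked)
    write.table(as.data.frame(curve), pth("ifs_curve.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    writeLines(sig$genes, pth("signature.txt"))
    cm <- sig$confusion
    st <- confusion_stats(cm)
    cmout <- rbind(unclass(cm), `Sample size` = st$sample_sizes,
                   Accuracy = round(st$per_class, 3))
    write.table(data.frame(predicted = rownames(cmout), cmout,
                           check.names = FALSE),
                pth("confusion.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
    manifest$ifs <- manifest_entry(
      "ifs", NA, unclass(cfg$classifier),
      list(pth("ifs_curve.tsv"), pth("signature.txt"), pth("confusion.tsv")),
      counts = list(k_star = sig$k_star, accuracy = sig$accuracy))
  }

  # -- enrichment ----------------------------------------------------------
  enr <- NULL
  if (!is.null(cfg$gene_sets) && length(sig$genes) > 0) {
    enr <- run_stage("enrich", verbose, {
      gsc <- read_gmt(cfg$gene_sets, universe = rownames(norm))
      enrich(sig$genes, gsc, cfg$fdr_threshold)
    })
    write.table(enr, pth("enrichment.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
    manifest$enrich <- manifest_entry(
      "enrich", NA, list(fdr_threshold = cfg$fdr_threshold),
      pth("enrichment.tsv"),
      counts = list(n_significant = sum(enr$significant)))
  }

  report <- structure(list(
    n_genes = nrow(norm),
    n_confirmed = length(confirmed),
    n_top_ranking = cutoff_k,
    k_star = sig$k_star,
    accuracy = sig$accuracy,
    signature = sig$genes,
    confusion = sig$confusion,
    planted_genes = dat$truth,
    enrichment = enr,
    output_dir = cfg$output_dir), class = "pipeline_report")
  jsonlite::write_json(manifest, pth("manifest.json"), auto_unbox = TRUE,
                       digits = NA, null = "null", force = TRUE)
  jsonlite::write_json(report[c("n_genes", "n_confirmed", "n_top_ranking",
                                "k_star", "accuracy", "signature")],
                       pth("report.json"), auto_unbox = TRUE, digits = NA,
                       null = "null")
  report
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read back the summary report of a finished pipeline run
#'
#' @param dir A pipeline output directory containing `report.json`.
#' @return The parsed report list.
#' @export
read_pipeline_report <- function(dir) {
  jsonlite::read_json(file.path(dir, "report.json"), simplifyVector = TRUE)
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("Signature-discovery funnel\n")
  cat(sprintf("  genes analyzed      : %d\n", x$n_genes))
  cat(sprintf("  Boruta-confirmed    : %d\n", x$n_confirmed))
  cat(sprintf("  top-ranking (MCFS)  : %d\n", x$n_top_ranking))
  cat(sprintf("  signature size k*   : %d\n", x$k_star))
  if (!is.na(x$accuracy))
    cat(sprintf("  LOOCV accuracy      : %.3f\n", x$accuracy))
  if (!is.null(x$enrichment))
    cat(sprintf("  enriched sets (FDR) : %d\n", sum(x$enrichment$significant)))
  invisible(x)
}
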