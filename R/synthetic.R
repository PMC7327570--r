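#' Configuration for the synthetic expression-data generator
#'
#' Describes a multi-class expression study with a small set of planted
#' class-discriminating genes inside a large noise background, optionally
#' measured on two "platforms" that differ by an additive batch offset.
#' The default class sizes (75/122/71/311) mirror a four-class blood
#' transcriptome design with definite-bacterial, definite-viral, healthy
#' control and Kawasaki-disease samples.
#'
#' @param class_sizes Positive integer samples per class (>= 2 classes);
#'   names, if present, are used as class labels.
#' @param n_genes Total number of genes.
#' @param n_informative Number of planted class-discriminating genes
#'   (`<= n_genes`).
#' @param effect_size Mean shift, in units of `noise_sd`, separating the
#'   elevated class from the rest on each planted gene.
#' @param noise_sd Standard deviation of additive Gaussian measurement noise.
#' @param batch_fraction Fraction of samples assigned to the second platform,
#'   in `[0, 1]`; the assignment is crossed with class.
#' @param batch_shift Additive offset applied to every gene of
#'   second-platform samples.
#' @param seed Integer RNG seed; identical configs generate identical data.
#' @return A `synthetic_config` list.
#' @export
synthetic_config <- function(class_sizes = c(DB = 75, DV = 122, HC = 71, KD = 311),
                             n_genes = 1000,
                             n_informative = 20,
                             effect_size = 3,
                             noise_sd = 1,
                             batch_fraction = 0.5,
                             batch_shift = 0,
                             seed = 1L) {
  if (length(class_sizes) < 2)
    stop_invalid("class_sizes must describe at least 2 classes")
  if (any(class_sizes < 1) || any(class_sizes != round(class_sizes)))
    stop_invalid("all class_sizes must be positive integers")
  if (n_genes < 1) stop_invalid("n_genes must be positive")
  if (n_informative < 0 || n_informative > n_genes)
    stop_invalid("n_informative must satisfy 0 <= n_informative <= n_genes")
  if (noise_sd <= 0) stop_invalid("noise_sd must be positive")
  if (effect_size < 0) stop_invalid("effect_size must be non-negative")
  if (batch_fraction < 0 || batch_fraction > 1)
    stop_invalid("batch_fraction must lie in [0, 1]")
  if (is.null(names(class_sizes)))
    names(class_sizes) <- paste0("class", seq_along(class_sizes))
  structure(list(class_sizes = class_sizes, n_genes = as.integer(n_genes),
                 n_informative = as.integer(n_informative),
                 effect_size = effect_size, noise_sd = noise_sd,
                 batch_fraction = batch_fraction, batch_shift = batch_shift,
                 seed = as.integer(seed)),
            class = "synthetic_config")
}

#' Generate a labeled synthetic expression dataset
#'
#' Every gene gets its own baseline intensity drawn from N(7, 1.5) (a
#' log-intensity scale typical of expression arrays); all measurements add
#' i.i.d. Gaussian noise with SD `noise_sd`.  Each planted gene designates
#' one "elevated" class, cycling over the classes so every class owns
#' discriminating genes; samples of that class have the gene's mean raised by
#' `effect_size * noise_sd`.  Non-informative genes are class-independent.
#' If `batch_fraction > 0`, a per-class random subset of samples is assigned
#' to a second platform (batch crossed with class, so batch never proxies for
#' class) and `batch_shift` is added to all their genes via
#' [apply_batch_effect()].
#'
#' @param config A [synthetic_config()].
#' @return A list of class `sig_dataset` with elements `matrix` (genes x
#'   samples), `labels` (named factor of classes keyed by sample ID), `truth`
#'   (list with `informative_genes` and `per_gene_class_means`), `batch`
#'   (named 0/1 platform assignment) and `config`.
#' @export
generate_dataset <- function(config) {
  if (!inherits(config, "synthetic_config"))
    config <- do.call(synthetic_config, config)
  cs <- config$class_sizes
  n <- sum(cs)
  K <- length(cs)
  classes <- names(cs)

  with_seed(config$seed, {
    gene_ids <- sprintf("g%05d", seq_len(config$n_genes))
    sample_ids <- sprintf("s%04d", seq_len(n))
    labels <- factor(rep(classes, times = cs), levels = classes)
    names(labels) <- sample_ids

    baseline <- rnorm(config$n_genes, mean = 7, sd = 1.5)
    m <- matrix(rnorm(config$n_genes * n, mean = 0, sd = config$noise_sd),
                nrow = config$n_genes, ncol = n,
                dimnames = list(gene_ids, sample_ids))
    m <- m + baseline

    informative <- character(0)
    means <- NULL
    if (config$n_informative > 0) {
      informative <- sort(sample(gene_ids, config$n_informative))
      elevated <- classes[(seq_along(informative) - 1L) %% K + 1L]
      shift <- config$effect_size * config$noise_sd
      for (i in seq_along(informative)) {
        sel <- labels == elevated[i]
        m[informative[i], sel] <- m[informative[i], sel] + shift
      }
      means <- data.frame(
        gene_id = rep(informative, each = K),
        class = rep(classes, times = length(informative)),
        true_mean = as.vector(vapply(seq_along(informative), function(i)
          baseline[match(informative[i], gene_ids)] +
            ifelse(classes == elevated[i], shift, 0),
          numeric(K))),
        stringsAsFactors = FALSE)
    } else {
      means <- data.frame(gene_id = character(0), class = character(0),
                          true_mean = numeric(0))
    }

    batch <- stats::setNames(integer(n), sample_ids)
    if (config$batch_fraction > 0) {
      # crossed with class: round(fraction * n_c) samples of each class
      for (cl in classes) {
        idx <- which(labels == cl)
        k <- round(config$batch_fraction * length(idx))
        if (k > 0) batch[sample(idx, k)] <- 1L
      }
      m <- apply_batch_effect(m, batch, config$batch_shift)
    }

    structure(list(matrix = m, labels = labels,
                   truth = list(informative_genes = informative,
                                per_gene_class_means = means),
                   batch = batch, config = config),
              class = "sig_dataset")
  })
}

#' Add an additive platform (batch) offset to selected samples
#'
#' @param m Numeric genes x samples matrix.
#' @param batch_assignment 0/1 vector, one entry per sample; samples flagged
#'   1 receive the offset on every gene.
#' @param shift Additive offset.
#' @return The shifted matrix, same dimensions.
#' @export
apply_batch_effect <- function(m, batch_assignment, shift) {
  assert_expression_matrix(m)
  if (length(batch_assignment) != ncol(m))
    stop_invalid("batch_assignment length (%d) differs from sample count (%d)",
                 length(batch_assignment), ncol(m))
  if (!all(batch_assignment %in% c(0, 1)))
    stop_invalid("batch_assignment must be a 0/1 vector")
  sel <- batch_assignment == 1
  m[, sel] <- m[, sel, drop = FALSE] + shift
  m
}

#' Write a synthetic dataset to a directory as plain-text files
#'
#' Writes `matrix.tsv`, `labels.tsv`, `truth.tsv`, `batch.tsv` and
#' `config.json`.
#'
#' @param ds A `sig_dataset`.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(ds, dir) {
  stopifnot(inherits(ds, "sig_dataset"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_expression_matrix(ds$matrix, file.path(dir, "matrix.tsv"))
  write_labels(ds$labels, file.path(dir, "labels.tsv"))
  write.table(ds$truth$per_gene_class_means, file.path(dir, "truth.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(data.frame(sample_id = names(ds$batch), batch = ds$batch),
              file.path(dir, "batch.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  cfg <- ds$config
  cfg$class_sizes <- as.list(cfg$class_sizes)
  jsonlite::write_json(unclass(cfg), file.path(dir, "config.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @export
print.sig_dataset <- function(x, ...) {
  cat(sprintf("Synthetic expression dataset: %d genes x %d samples\n",
              nrow(x$matrix), ncol(x$matrix)))
  cat("  classes:",
      paste(sprintf("%s (n=%d)", levels(x$labels), table(x$labels)),
            collapse = ", "), "\n")
  cat(sprintf("  planted informative genes: %d; batch-1 samples: %d\n",
              length(x$truth$informative_genes), sum(x$batch)))
  invisible(x)
}
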