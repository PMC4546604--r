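#' Ranksum high/low sample labelling
#'
#' Orders tumour samples by the sum of their expression rank and copy-number
#' rank (average ranks on ties) and labels the extremes: in `"extremes"` mode
#' the top `floor(top_fraction * n)` samples are `"high"`, the same number at
#' the bottom `"low"`, and the rest `"unlabeled"`; in `"all"` mode every
#' sample is labelled by a median split of the ranksum (ties at the median go
#' to `"low"`). Ranksum ties at a labelling boundary are broken by sample
#' identifier order, with a warning.
#'
#' @param data Tibble with columns `sample`, `expression`, `copy_number`.
#' @param top_fraction Fraction labelled per class in extremes mode
#'   (default 0.10).
#' @param mode `"extremes"` or `"all"`.
#' @return A tibble with `sample`, `ranksum`, `label`.
#' @examples
#' d <- tibble::tibble(sample = letters[1:5],
#'                     expression = 5:1, copy_number = 5:1)
#' ranksum_label(d, top_fraction = 0.2)
#' @export
ranksum_label <- function(data, top_fraction = 0.10,
                          mode = c("extremes", "all")) {
  mode <- match.arg(mode)
  need <- c("sample", "expression", "copy_number")
  missing <- setdiff(need, names(data))
  if (length(missing) > 0) {
    abort(paste0("`data` is missing column(s): ", paste(missing, collapse = ", ")))
  }
  if (top_fraction <= 0 || top_fraction > 0.5) {
    abort("`top_fraction` must lie in (0, 0.5].")
  }
  n <- nrow(data)
  rs <- rank(data$expression, ties.method = "average") +
    rank(data$copy_number, ties.method = "average")
  label <- rep("unlabeled", n)
  if (mode == "extremes") {
    n_lab <- floor(top_fraction * n)
    if (n_lab < 1) abort("Too few samples to label at this `top_fraction`.")
    # sort ascending by (ranksum, sample id): bottom n_lab low, top n_lab high
    ord <- order(rs, data$sample)
    lo_set <- ord[seq_len(n_lab)]
    hi_set <- ord[seq(n - n_lab + 1, n)]
    if (max(rs[lo_set]) >= min(rs[hi_set]) ||
        any(rs[lo_set] %in% rs[-lo_set]) || any(rs[hi_set] %in% rs[-hi_set])) {
      warn("Ranksum ties at a labelling boundary; broken by sample id order.")
    }
    label[lo_set] <- "low"
    label[hi_set] <- "high"
  } else {
    label <- ifelse(rs > median(rs), "high", "low")
    if (all(label == "low") || all(label == "high")) {
      warn("Degenerate median split: all samples on one side.")
    }
  }
  tibble(sample = data$sample, ranksum = rs, label = label)
}

as_expr_matrix <- function(expr) {
  if (is.matrix(expr)) {
    if (is.null(rownames(expr)) || is.null(colnames(expr))) {
      abort("Expression matrix needs gene rownames and sample colnames.")
    }
    return(expr)
  }
  if (is.data.frame(expr)) {
    if (!"gene_id" %in% names(expr)) {
      abort("Expression data frame needs a `gene_id` column.")
    }
    m <- as.matrix(expr[, setdiff(names(expr), "gene_id"), drop = FALSE])
    rownames(m) <- expr$gene_id
    return(m)
  }
  abort("`expr` must be a matrix or a data frame with a gene_id column.")
}

#' Fit a Gaussian naive Bayes expression classifier
#'
#' Per-gene class-conditional Gaussians: for each gene and each class
#' (`"high"`, `"low"`) the unbiased mean and variance over training samples,
#' with variances floored at `var_floor_factor` times the global expression
#' variance so constant genes cannot produce degenerate densities. Class
#' priors are the training class frequencies. Expression values are
#' `log2(x + 1)`-transformed by default, which makes the Gaussian model
#' plausible for FPKM-like data.
#'
#' @param expr Genes-by-samples matrix (gene rownames, sample colnames) or a
#'   tibble with a `gene_id` column and one column per sample.
#' @param labels Labelling tibble (see [ranksum_label()]); only samples
#'   labelled `"high"`/`"low"` are used, and at least two per class are
#'   required.
#' @param log2_transform Apply `log2(x + 1)` before fitting (default TRUE).
#' @param var_floor_factor Variance floor as a fraction of the global
#'   variance (default `1e-9`).
#' @return An `nb_model` object; see [tidy.nb_model()] and
#'   [glance.nb_model()].
#' @export
nb_fit <- function(expr, labels, log2_transform = TRUE,
                   var_floor_factor = 1e-9) {
  m <- as_expr_matrix(expr)
  lab <- labels[labels$label %in% c("high", "low"), ]
  missing <- setdiff(lab$sample, colnames(m))
  if (length(missing) > 0) {
    abort(paste0("Labelled sample(s) absent from matrix: ",
                 paste(utils::head(missing, 5), collapse = ", ")))
  }
  cls <- split(lab$sample, lab$label)
  if (length(cls) < 2 || any(lengths(cls) < 2)) {
    abort("Need at least two training samples in each of 'high' and 'low'.")
  }
  m <- m[, lab$sample, drop = FALSE]
  if (log2_transform) m <- log2(m + 1)
  floor_eps <- max(var_floor_factor * var(as.vector(m)), .Machine$double.xmin)
  params <- lapply(c(high = "high", low = "low"), function(cl) {
    sub <- m[, cls[[cl]], drop = FALSE]
    mu <- rowMeans(sub)
    v <- apply(sub, 1, var)
    list(mean = mu, var = pmax(v, floor_eps))
  })
  structure(
    list(
      genes = rownames(m),
      mean_high = params$high$mean, var_high = params$high$var,
      mean_low = params$low$mean, var_low = params$low$var,
      prior_high = length(cls$high) / nrow(lab),
      prior_low = length(cls$low) / nrow(lab),
      log2_transform = log2_transform,
      var_floor = floor_eps,
      n_train = nrow(lab)
    ),
    class = "nb_model"
  )
}

#' @export
print.nb_model <- function(x, ...) {
  cat("<nb_model> Gaussian naive Bayes: ", length(x$genes), " genes, ",
      x$n_train, " training samples (prior high = ",
      signif(x$prior_high, 3), ")\n", sep = "")
  invisible(x)
}

#' Posterior probability of the "high" class
#'
#' Scores samples with a fitted Gaussian naive Bayes model. Posteriors are
#' computed in log space (sum of per-gene Gaussian log-densities plus the
#' log-prior, normalised across the two classes), so long gene signatures do
#' not underflow.
#'
#' @param model An `nb_model` from [nb_fit()].
#' @param expr Matrix or tibble of expression for the samples to score; must
#'   contain all model genes.
#' @return A tibble with `sample`, `posterior_high`.
#' @export
nb_predict <- function(model, expr) {
  m <- as_expr_matrix(expr)
  missing <- setdiff(model$genes, rownames(m))
  if (length(missing) > 0) {
    abort(paste0("Model gene(s) absent from matrix: ",
                 paste(utils::head(missing, 5), collapse = ", ")))
  }
  m <- m[model$genes, , drop = FALSE]
  if (model$log2_transform) m <- log2(m + 1)
  log_lik <- function(mu, v) {
    colSums(stats::dnorm(m, mean = mu, sd = sqrt(v), log = TRUE))
  }
  lh <- log_lik(model$mean_high, model$var_high) + log(model$prior_high)
  ll <- log_lik(model$mean_low, model$var_low) + log(model$prior_low)
  mx <- pmax(lh, ll)
  post <- exp(lh - mx) / (exp(lh - mx) + exp(ll - mx))
  tibble(sample = colnames(m), posterior_high = unname(post))
}

#' Area under the ROC curve
#'
#' Mann-Whitney formulation: the fraction of (high, low) sample pairs in
#' which the high sample receives the larger score, ties counted one half.
#'
#' @param scores Numeric scores (larger = more "high").
#' @param labels Class labels; `"high"`/`TRUE`/1 = positive,
#'   `"low"`/`FALSE`/0 = negative.
#' @return AUC in \[0, 1\].
#' @export
auc_score <- function(scores, labels) {
  if (is.character(labels) || is.factor(labels)) {
    pos <- as.character(labels) == "high"
  } else {
    pos <- as.logical(labels)
  }
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0 || n0 == 0) abort("Both classes must be present to compute AUC.")
  r <- rank(scores, ties.method = "average")
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Signature gene selection by standardised mean difference
#'
#' Ranks genes by the absolute difference of class means divided by the
#' pooled standard deviation, and returns the top `k`. Ties are broken by
#' gene identifier so the selection is deterministic.
#'
#' @param expr Expression matrix or tibble (see [nb_fit()]).
#' @param labels Labelling tibble; only `"high"`/`"low"` samples are used.
#' @param k Number of genes to keep (default 10).
#' @param log2_transform Apply `log2(x + 1)` first (default TRUE).
#' @return Character vector of `k` gene ids.
#' @export
select_features <- function(expr, labels, k = 10, log2_transform = TRUE) {
  m <- as_expr_matrix(expr)
  if (k > nrow(m)) abort("`k` exceeds the number of genes.")
  lab <- labels[labels$label %in% c("high", "low"), ]
  m <- m[, lab$sample, drop = FALSE]
  if (log2_transform) m <- log2(m + 1)
  hi <- m[, lab$label == "high", drop = FALSE]
  lo <- m[, lab$label == "low", drop = FALSE]
  n1 <- ncol(hi); n0 <- ncol(lo)
  v1 <- apply(hi, 1, var); v0 <- apply(lo, 1, var)
  pooled_sd <- sqrt(((n1 - 1) * v1 + (n0 - 1) * v0) / (n1 + n0 - 2))
  pooled_sd[pooled_sd == 0] <- .Machine$double.eps
  smd <- abs(rowMeans(hi) - rowMeans(lo)) / pooled_sd
  ord <- order(-smd, rownames(m))
  rownames(m)[ord[seq_len(k)]]
}

#' Iterated random-holdout evaluation of the signature classifier
#'
#' Repeats, `n_iterations` times: split the labelled samples into training
#' and test subsets (stratified by class so both classes survive every
#' split), fit the Gaussian naive Bayes model on the training subset —
#' optionally after selecting the top `select_k` signature genes on the
#' training data only — score the test subset, and record the ROC AUC. The
#' per-iteration AUCs and their mean summarise how well the expression
#' signature predicts the high/low labels.
#'
#' @param expr Expression matrix or tibble (see [nb_fit()]).
#' @param labels Labelling tibble (see [ranksum_label()]).
#' @param signature_genes Genes to use (default: all genes in `expr`); an
#'   error lists any that are absent from the matrix.
#' @param n_iterations Number of random splits (default 1000).
#' @param train_fraction Fraction of each class used for training
#'   (default 2/3).
#' @param seed Integer seed; fixing it makes the whole evaluation
#'   deterministic.
#' @param select_k If non-NULL, per-iteration training-fold feature selection
#'   down to this many genes (see [select_features()]).
#' @param log2_transform Passed to [nb_fit()].
#' @return An `nb_cv` object with per-iteration AUCs; see [tidy.nb_cv()] and
#'   [glance.nb_cv()].
#' @export
iterated_holdout <- function(expr, labels, signature_genes = NULL,
                             n_iterations = 1000, train_fraction = 2 / 3,
                             seed = NULL, select_k = NULL,
                             log2_transform = TRUE) {
  m <- as_expr_matrix(expr)
  if (!is.null(signature_genes)) {
    missing <- setdiff(signature_genes, rownames(m))
    if (length(missing) > 0) {
      abort(paste0("Signature gene(s) absent from matrix: ",
                   paste(missing, collapse = ", ")))
    }
    m <- m[signature_genes, , drop = FALSE]
  }
  lab <- labels[labels$label %in% c("high", "low"), ]
  if (train_fraction <= 0 || train_fraction >= 1) {
    abort("`train_fraction` must lie in (0, 1).")
  }
  by_class <- split(lab$sample, lab$label)
  n_train <- vapply(by_class, function(s) max(2, round(train_fraction * length(s))),
                    numeric(1))
  if (any(n_train >= lengths(by_class))) {
    abort("Too few samples per class for this `train_fraction`.")
  }
  aucs <- with_optional_seed(seed, {
    vapply(seq_len(n_iterations), function(it) {
      train_samples <- unlist(lapply(names(by_class), function(cl) {
        sample(by_class[[cl]], n_train[[cl]])
      }))
      test_samples <- setdiff(lab$sample, train_samples)
      train_lab <- lab[lab$sample %in% train_samples, ]
      genes <- if (is.null(select_k)) rownames(m) else {
        select_features(m[, train_samples, drop = FALSE], train_lab,
                        k = select_k, log2_transform = log2_transform)
      }
      fit <- nb_fit(m[genes, train_samples, drop = FALSE], train_lab,
                    log2_transform = log2_transform)
      pred <- nb_predict(fit, m[genes, test_samples, drop = FALSE])
      truth <- lab$label[match(pred$sample, lab$sample)]
      auc_score(pred$posterior_high, truth)
    }, numeric(1))
  })
  structure(
    list(auc = aucs, mean_auc = mean(aucs), n_iterations = n_iterations,
         train_fraction = train_fraction, seed = seed,
         select_k = select_k, n_genes = nrow(m), n_samples = nrow(lab)),
    class = "nb_cv"
  )
}

#' @export
print.nb_cv <- function(x, ...) {
  cat("<nb_cv> ", x$n_iterations, " random holdout iterations (train fraction ",
      signif(x$train_fraction, 3), ", ", x$n_genes, " genes, ", x$n_samples,
      " labelled samples)\n  mean AUC = ", signif(x$mean_auc, 4), "\n", sep = "")
  invisible(x)
}

#' Tidy per-gene naive Bayes parameters
#'
#' @param x An `nb_model`.
#' @param ... Unused.
#' @return A tibble with one row per gene: class-conditional means and
#'   variances.
#' @export
tidy.nb_model <- function(x, ...) {
  tibble(
    gene_id = x$genes,
    mean_high = unname(x$mean_high), var_high = unname(x$var_high),
    mean_low = unname(x$mean_low), var_low = unname(x$var_low)
  )
}

#' One-row naive Bayes model summary
#'
#' @param x An `nb_model`.
#' @param ... Unused.
#' @return A one-row tibble: gene count, priors, training size, variance
#'   floor.
#' @export
glance.nb_model <- function(x, ...) {
  tibble(
    n_genes = length(x$genes), prior_high = x$prior_high,
    prior_low = x$prior_low, n_train = x$n_train, var_floor = x$var_floor
  )
}

#' Per-iteration holdout AUCs
#'
#' @param x An `nb_cv`.
#' @param ... Unused.
#' @return A tibble with `iteration`, `auc`.
#' @export
tidy.nb_cv <- function(x, ...) {
  tibble(iteration = seq_along(x$auc), auc = x$auc)
}

#' One-row holdout evaluation summary
#'
#' @param x An `nb_cv`.
#' @param ... Unused.
#' @return A one-row tibble: mean/sd AUC, iteration count, configuration.
#' @export
glance.nb_cv <- function(x, ...) {
  tibble(
    mean_auc = x$mean_auc, sd_auc = sd(x$auc),
    n_iterations = x$n_iterations, train_fraction = x$train_fraction,
    n_genes = x$n_genes, n_samples = x$n_samples
  )
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance
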