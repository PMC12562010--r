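## ---------------------------------------------------------------------------
## Pair construction, variant filtering, data splits, and the end-to-end
## training loop with edge masking and validation-loss model selection.
## ---------------------------------------------------------------------------

.allowed_review_status <- c(
  "practice guideline",
  "reviewed by expert panel",
  "criteria provided, multiple submitters, no conflicts",
  "criteria provided, single submitter"
)

.nuclear_chroms <- c(as.character(1:22), "X", "Y")

#' ClinVar-style record filtering
#'
#' Keeps exactly the records with clinical label `benign` or `pathogenic`,
#' review status among the four accepted tiers, germline origin, GRCh38
#' coordinates, a nonempty gene symbol, and a nuclear chromosome (1-22, X,
#' Y). Rules are applied in that order and the number of records dropped by
#' each rule is attached as attribute `drop_counts`.
#'
#' @param variants Variant table with columns `clinical_label`,
#'   `review_status`, `origin`, `assembly`, `gene`, `chrom`.
#' @return The filtered variant table (attribute `drop_counts`).
#' @export
filter_clinvar_records <- function(variants) {
  variants <- as.data.frame(variants, stringsAsFactors = FALSE)
  need <- c("clinical_label", "review_status", "origin", "assembly", "gene",
            "chrom")
  miss <- setdiff(need, names(variants))
  if (length(miss)) {
    stop("variant table misses required field(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  rules <- list(
    label = function(df) df$clinical_label %in% c("benign", "pathogenic"),
    review_status = function(df) df$review_status %in% .allowed_review_status,
    origin = function(df) df$origin == "germline",
    assembly = function(df) df$assembly == "GRCh38",
    gene = function(df) !is.na(df$gene) & nzchar(trimws(df$gene)),
    chromosome = function(df) df$chrom %in% .nuclear_chroms
  )
  drops <- stats::setNames(integer(length(rules)), names(rules))
  for (nm in names(rules)) {
    keep <- rules[[nm]](variants)
    drops[[nm]] <- sum(!keep)
    variants <- variants[keep, , drop = FALSE]
  }
  rownames(variants) <- NULL
  attr(variants, "drop_counts") <- drops
  variants
}

#' Build labelled variant-disease pair examples
#'
#' Positives pair every pathogenic variant with each of its associated
#' diseases (label 1). Negatives pair every benign variant with every
#' disease connected to its gene through a `Disease-Gene` edge (label 0).
#' Benign variants whose gene carries no disease edge contribute nothing and
#' are counted in attribute `n_benign_skipped`.
#'
#' @param graph A `hetero_graph` with the variants attached
#'   (see [attach_variants()]).
#' @param variants The variant table that was attached.
#' @return data.frame (`variant_id`, `disease_id`, `label`, `gene`).
#' @export
build_pairs <- function(graph, variants) {
  stopifnot(inherits(graph, "hetero_graph"))
  variants <- as.data.frame(variants, stringsAsFactors = FALSE)
  empty <- data.frame(variant_id = character(), disease_id = character(),
                      label = integer(), gene = character(),
                      stringsAsFactors = FALSE)
  if (!nrow(variants)) {
    attr(empty, "n_benign_skipped") <- 0L
    return(empty)
  }
  genes <- graph$nodes[graph$nodes$node_type == "gene", , drop = FALSE]
  gene_id_of <- stats::setNames(genes$node_id, genes$name)
  dis <- graph$nodes[graph$nodes$node_type == "disease", , drop = FALSE]
  dis_id_of <- stats::setNames(dis$node_id, .norm_disease_key(dis$name))

  dg <- graph$edges[graph$edges$edge_type == "Disease-Gene (associated with)",
                    , drop = FALSE]
  is_dis <- dg$src %in% dis$node_id
  dg_gene <- ifelse(is_dis, dg$dst, dg$src)
  dg_dis <- ifelse(is_dis, dg$src, dg$dst)

  vid <- variant_id(variants$chrom, variants$pos, variants$ref, variants$alt)
  rows <- vector("list", nrow(variants))
  n_skipped <- 0L
  for (i in seq_len(nrow(variants))) {
    g <- variants$gene[i]
    lab <- variants$clinical_label[i]
    if (identical(lab, "pathogenic")) {
      ds <- .split_diseases(variants$diseases[i])
      if (!length(ds)) next
      d_ids <- unname(dis_id_of[.norm_disease_key(ds)])
      if (anyNA(d_ids)) {
        stop("pathogenic variant '", vid[i], "' names a disease absent from ",
             "the graph; attach variants first", call. = FALSE)
      }
      rows[[i]] <- data.frame(variant_id = vid[i], disease_id = d_ids,
                              label = 1L, gene = g, stringsAsFactors = FALSE)
    } else if (identical(lab, "benign")) {
      d_ids <- unique(dg_dis[dg_gene == gene_id_of[[g]]])
      if (!length(d_ids)) {
        n_skipped <- n_skipped + 1L
        warning("benign variant '", vid[i],
                "' in gene without disease edges yields no pairs")
        next
      }
      rows[[i]] <- data.frame(variant_id = vid[i], disease_id = d_ids,
                              label = 0L, gene = g, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, c(list(empty), rows[!vapply(rows, is.null, TRUE)]))
  rownames(out) <- NULL
  key <- paste(out$variant_id, out$disease_id, out$label)
  out <- out[!duplicated(key), , drop = FALSE]
  attr(out, "n_benign_skipped") <- n_skipped
  out
}

.as_split <- function(train, validation, test) {
  structure(list(train = train, validation = validation, test = test),
            class = "patho_split")
}

#' @export
print.patho_split <- function(x, ...) {
  cat("Variant-disease pair split: train", nrow(x$train), "/ validation",
      nrow(x$validation), "/ test", nrow(x$test), "\n")
  invisible(x)
}

#' Random 70/15/15 split of pair examples
#'
#' Seeded shuffle followed by a contiguous partition; validation and test
#' sizes are floors of their fractions, the remainder goes to training.
#'
#' @param pairs Pair table from [build_pairs()].
#' @param fractions Train/validation/test fractions summing to 1.
#' @param seed Integer seed (RNG state is restored afterwards).
#' @return A `patho_split`.
#' @export
random_split <- function(pairs, fractions = c(0.70, 0.15, 0.15), seed = 1L) {
  stopifnot(abs(sum(fractions) - 1) < 1e-8, length(fractions) == 3L)
  n <- nrow(pairs)
  if (n < 3L) stop("degenerate split: fewer than 3 pairs", call. = FALSE)
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(as.integer(seed))
  idx <- sample.int(n)
  n_val <- floor(n * fractions[2L])
  n_test <- floor(n * fractions[3L])
  n_train <- n - n_val - n_test
  .as_split(pairs[idx[seq_len(n_train)], , drop = FALSE],
            pairs[idx[n_train + seq_len(n_val)], , drop = FALSE],
            pairs[idx[n_train + n_val + seq_len(n_test)], , drop = FALSE])
}

#' Per-gene class-balanced split
#'
#' For every gene, one variant is reserved for validation and one for
#' testing, drawn from different classes (pathogenic vs benign) when both
#' classes are present; a single-variant gene sends its variant to training
#' with a warning. The remaining variants' pairs enter training with the
#' per-gene positive and negative pair counts matched exactly at the smaller
#' of the two (surplus majority-class pairs are left out and counted in
#' attribute `n_left_out`).
#'
#' @param variants Variant table (filtered, attached to `graph`).
#' @param graph A `hetero_graph` with variants attached.
#' @param seed Integer seed.
#' @return A `patho_split` with per-gene balanced training pairs.
#' @export
per_gene_balanced_split <- function(variants, graph, seed = 1L) {
  variants <- as.data.frame(variants, stringsAsFactors = FALSE)
  all_pairs <- build_pairs(graph, variants)
  vid <- variant_id(variants$chrom, variants$pos, variants$ref, variants$alt)
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(as.integer(seed))

  train <- list(); val <- list(); test <- list()
  n_left_out <- 0L
  for (g in sort(unique(variants$gene))) {
    gi <- which(variants$gene == g)
    gv <- vid[gi]
    glab <- variants$clinical_label[gi]
    if (length(gi) == 1L) {
      warning("gene '", g, "' has a single variant; assigned to training")
      train_ids <- gv
      eval_ids <- character()
    } else {
      path_ids <- gv[glab == "pathogenic"]
      ben_ids <- gv[glab == "benign"]
      if (length(path_ids) && length(ben_ids)) {
        picks <- c(path_ids[sample.int(length(path_ids), 1L)],
                   ben_ids[sample.int(length(ben_ids), 1L)])
        picks <- picks[sample.int(2L)]
      } else {
        picks <- gv[sample.int(length(gv), 2L)]
      }
      eval_ids <- picks
      train_ids <- setdiff(gv, picks)
    }
    val[[g]] <- all_pairs[all_pairs$variant_id %in% eval_ids[1L], ,
                          drop = FALSE]
    if (length(eval_ids) > 1L) {
      test[[g]] <- all_pairs[all_pairs$variant_id %in% eval_ids[2L], ,
                             drop = FALSE]
    }
    gp <- all_pairs[all_pairs$variant_id %in% train_ids, , drop = FALSE]
    pos <- which(gp$label == 1L)
    neg <- which(gp$label == 0L)
    m <- min(length(pos), length(neg))
    n_left_out <- n_left_out + (length(pos) - m) + (length(neg) - m)
    if (m > 0L) {
      keep <- c(if (length(pos) > m) pos[sample.int(length(pos), m)] else pos,
                if (length(neg) > m) neg[sample.int(length(neg), m)] else neg)
      train[[g]] <- gp[sort(keep), , drop = FALSE]
    }
  }
  bind <- function(lst) {
    out <- do.call(rbind, c(list(all_pairs[0, ]), lst))
    rownames(out) <- NULL
    out
  }
  sp <- .as_split(bind(train), bind(val), bind(test))
  attr(sp, "n_left_out") <- n_left_out
  sp
}

#' Date-based forward-in-time split
#'
#' Pairs from variants submitted up to the end of `cutoff_year` are split
#' 80/20 into training and validation (seeded); pairs from later variants
#' form the test set, simulating deployment on future submissions. Undated
#' variants are excluded and counted in attribute `n_undated`.
#'
#' @param variants Variant table with `submission_date` (ISO dates).
#' @param graph A `hetero_graph` with variants attached.
#' @param cutoff_year Last training/validation year (default 2022).
#' @param val_fraction Validation share of the pre-cutoff pairs.
#' @param seed Integer seed.
#' @return A `patho_split`.
#' @export
date_split <- function(variants, graph, cutoff_year = 2022L,
                       val_fraction = 0.2, seed = 1L) {
  variants <- as.data.frame(variants, stringsAsFactors = FALSE)
  sd_raw <- as.character(variants$submission_date)
  dated <- !is.na(sd_raw) & nzchar(trimws(sd_raw))
  dates <- rep(as.Date(NA), length(sd_raw))
  dates[dated] <- as.Date(sd_raw[dated])
  undated <- is.na(dates)
  variants <- variants[!undated, , drop = FALSE]
  dates <- dates[!undated]
  cutoff <- as.Date(paste0(cutoff_year, "-12-31"))
  pre <- dates <= cutoff
  if (!any(!pre)) stop("no post-cutoff variants: empty test set",
                       call. = FALSE)
  pre_pairs <- build_pairs(graph, variants[pre, , drop = FALSE])
  test <- build_pairs(graph, variants[!pre, , drop = FALSE])
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(as.integer(seed))
  n <- nrow(pre_pairs)
  idx <- sample.int(n)
  n_val <- floor(n * val_fraction)
  sp <- .as_split(pre_pairs[idx[seq_len(n - n_val)], , drop = FALSE],
                  pre_pairs[idx[n - n_val + seq_len(n_val)], , drop = FALSE],
                  test)
  attr(sp, "n_undated") <- sum(undated)
  sp
}

## ---------------------------------------------------------------------------
## Model fitting
## ---------------------------------------------------------------------------

#' Training control parameters
#'
#' Defaults are the published learning setup: stochastic gradient descent
#' with learning rate 0.001, weight decay 0.1 and momentum 0.9, dropout 0.3,
#' classification threshold 0.5, full-batch updates, and validation-loss
#' model selection (argmin over epochs) with early-stopping patience.
#'
#' @param learning_rate,weight_decay,momentum SGD hyperparameters.
#' @param epochs Maximum number of full-batch epochs.
#' @param patience Early-stopping patience on validation loss (counted in
#'   evaluated epochs).
#' @param val_every Evaluate the validation loss every this many epochs
#'   (model selection still takes the argmin over evaluated epochs).
#' @param dropout Dropout rate during training.
#' @param threshold Sigmoid classification threshold.
#' @param seed Integer seed driving initialisation and dropout.
#' @param mask_disease_variant Mask Disease-Variant edges in every adjacency
#'   used during training (leakage guard; disable only for diagnostics).
#' @param encoder_dims,decoder_dims Hidden widths of encoder and decoder.
#' @param baseline_hidden Hidden widths of the no-graph baselines.
#' @return List of class `patho_control`.
#' @export
patho_control <- function(learning_rate = 0.001, weight_decay = 0.1,
                          momentum = 0.9, epochs = 200L, patience = 30L,
                          val_every = 1L, dropout = 0.3, threshold = 0.5,
                          seed = 1L, mask_disease_variant = TRUE,
                          encoder_dims = c(256L, 64L),
                          decoder_dims = c(64L, 32L),
                          baseline_hidden = c(256L, 64L)) {
  structure(list(learning_rate = learning_rate, weight_decay = weight_decay,
                 momentum = momentum, epochs = as.integer(epochs),
                 patience = as.integer(patience),
                 val_every = as.integer(val_every), dropout = dropout,
                 threshold = threshold, seed = as.integer(seed),
                 mask_disease_variant = mask_disease_variant,
                 encoder_dims = as.integer(encoder_dims),
                 decoder_dims = as.integer(decoder_dims),
                 baseline_hidden = as.integer(baseline_hidden)),
            class = "patho_control")
}

#' Desk-scale synthetic-validation control
#'
#' The published learning setup (learning rate 0.001, weight decay 0.1 under
#' mean-loss coupling) was calibrated for a corpus of several hundred
#' thousand pairs. On desk-scale synthetic fixtures (a few thousand pairs,
#' full-batch updates) that weight decay provably admits only the trivial
#' base-rate predictor -- the ridge-equivalent optimum never crosses the 0.5
#' decision threshold -- and that learning rate needs on the order of 10^4
#' full-batch epochs. This control therefore drops the decay term and scales
#' the step size to the affordable update budget (see the methods vignette
#' for the analysis); architecture, momentum, dropout, threshold and the
#' selection rule are unchanged. Used by the package's planted-signal
#' validation experiments; [patho_control()] keeps the published defaults.
#'
#' @param seed Integer seed.
#' @param epochs Full-batch epochs (300 suffices for signal recovery on the
#'   reference fixture).
#' @param val_every Validation-loss evaluation interval.
#' @param ... Further overrides passed to [patho_control()].
#' @return A `patho_control` list.
#' @export
patho_validation_control <- function(seed = 1L, epochs = 300L,
                                     val_every = 5L, ...) {
  patho_control(learning_rate = 0.05, weight_decay = 0, epochs = epochs,
                patience = epochs, val_every = val_every, seed = seed, ...)
}

.pair_indices <- function(pairs, ids) {
  iv <- match(pairs$variant_id, ids)
  idd <- match(pairs$disease_id, ids)
  if (anyNA(iv) || anyNA(idd)) {
    bad <- c(pairs$variant_id[is.na(iv)], pairs$disease_id[is.na(idd)])
    stop("pair endpoint not present in graph: '", bad[[1L]], "'",
         call. = FALSE)
  }
  list(iv = iv, idd = idd, y = as.numeric(pairs$label))
}

#' Fit the disease-specific pathogenicity model
#'
#' Trains the selected architecture end-to-end with full-batch SGD on binary
#' cross-entropy over the training pairs, records train/validation losses
#' per epoch, and returns the parameter state with minimum validation loss.
#' For the graph model, Disease-Variant edges are masked in the adjacency
#' used by every forward pass and their absence is asserted at every epoch.
#'
#' @param graph A `hetero_graph` with variants attached.
#' @param features Assembled initial feature matrix
#'   (see [assemble_initial_features()]); rows must follow [node_order()].
#' @param split A `patho_split`.
#' @param model `"gcn"` (graph encoder + pair decoder), `"baseline_pair"`
#'   (raw-embedding disease-specific network) or `"baseline_variant"`
#'   (raw-embedding variant-only network).
#' @param control A [patho_control()] list.
#' @return Object of class `patho_fit` with `print`, `summary`, `coef`,
#'   `predict`, `plot`, `fitted` and `residuals` methods.
#' @export
patho_fit <- function(graph, features, split, model = c("gcn",
                      "baseline_pair", "baseline_variant"),
                      control = patho_control()) {
  model <- match.arg(model)
  stopifnot(inherits(graph, "hetero_graph"), inherits(split, "patho_split"),
            inherits(control, "patho_control"))
  ids <- node_order(graph)
  if (!identical(rownames(features), ids)) {
    stop("feature rows must follow the canonical node order", call. = FALSE)
  }
  .assert_disjoint_split(split)

  if (control$mask_disease_variant) {
    graph <- mask_edges(graph, "Disease-Variant (associated with)")
  }
  A_hat <- if (model == "gcn") normalized_adjacency(graph) else NULL

  tr <- .pair_indices(split$train, ids)
  va <- .pair_indices(split$validation, ids)

  old <- .save_rng(); on.exit(.restore_rng(old))
  if (model == "gcn") {
    params <- init_patho_params(ncol(features), control$encoder_dims,
                                control$decoder_dims, seed = control$seed)
  } else {
    in_dim <- if (model == "baseline_pair") 2L * ncol(features) else
      ncol(features)
    params <- init_baseline_params(in_dim, control$baseline_hidden,
                                   seed = control$seed)
  }
  set.seed(control$seed + 1L)  # dropout stream

  fwd_train <- function(p) {
    if (model == "gcn") {
      .full_forward_backward(features, A_hat, tr$iv, tr$idd, tr$y, p,
                             training = TRUE, dropout = control$dropout)
    } else {
      U <- .baseline_input(features, tr, model)
      .baseline_forward_backward(U, tr$y, p, training = TRUE,
                                 dropout = control$dropout)
    }
  }
  loss_eval <- function(p, ix) {
    if (model == "gcn") {
      .full_forward_backward(features, A_hat, ix$iv, ix$idd, ix$y, p,
                             training = FALSE, want_grads = FALSE)$loss
    } else {
      U <- .baseline_input(features, ix, model)
      .baseline_forward_backward(U, ix$y, p, training = FALSE,
                                 want_grads = FALSE)$loss
    }
  }

  velocity <- .zero_like(params)
  history <- data.frame(epoch = integer(), train_loss = numeric(),
                        val_loss = numeric())
  best_params <- params
  best_val <- loss_eval(params, va)
  best_epoch <- 0L
  since_best <- 0L

  for (epoch in seq_len(control$epochs)) {
    if (model == "gcn" && control$mask_disease_variant) {
      # leakage guard, asserted every epoch
      if ("Disease-Variant (associated with)" %in%
          active_edges(graph)$edge_type) {
        stop("leakage: Disease-Variant edges present in training adjacency",
             call. = FALSE)
      }
    }
    step <- fwd_train(params)
    if (!is.finite(step$loss)) {
      stop("non-finite training loss at epoch ", epoch, " (lr = ",
           control$learning_rate, "); aborting", call. = FALSE)
    }
    upd <- .sgd_step(params, step$grads, velocity, control$learning_rate,
                     control$momentum, control$weight_decay)
    params <- upd$params
    velocity <- upd$velocity

    # train loss from the pre-update training-mode pass (standard practice;
    # avoids a third full forward per epoch), validation loss in eval mode
    if (epoch %% control$val_every == 0L || epoch == control$epochs) {
      tl <- step$loss
      vl <- loss_eval(params, va)
      history <- rbind(history, data.frame(epoch = epoch, train_loss = tl,
                                           val_loss = vl))
      if (vl < best_val) {
        best_val <- vl
        best_params <- params
        best_epoch <- epoch
        since_best <- 0L
      } else {
        since_best <- since_best + 1L
        if (since_best >= control$patience) break
      }
    }
  }

  structure(list(model = model, params = best_params, best_epoch = best_epoch,
                 best_val_loss = best_val, history = history,
                 control = control, graph = graph, features = features,
                 A_hat = A_hat, split = split, node_ids = ids),
            class = "patho_fit")
}

.baseline_input <- function(features, ix, model) {
  if (model == "baseline_pair") {
    cbind(features[ix$iv, , drop = FALSE], features[ix$idd, , drop = FALSE])
  } else {
    features[ix$iv, , drop = FALSE]
  }
}

.assert_disjoint_split <- function(split) {
  key <- function(p) paste(p$variant_id, p$disease_id)
  ks <- list(key(split$train), key(split$validation), key(split$test))
  if (length(intersect(ks[[1]], ks[[2]])) ||
      length(intersect(ks[[1]], ks[[3]])) ||
      length(intersect(ks[[2]], ks[[3]]))) {
    stop("split partitions are not disjoint", call. = FALSE)
  }
  invisible(TRUE)
}

#' @export
print.patho_fit <- function(x, ...) {
  cat("Disease-specific pathogenicity model (", x$model, ")\n", sep = "")
  cat("  trained epochs:", if (nrow(x$history)) max(x$history$epoch) else 0L,
      " selected epoch:", x$best_epoch,
      " (validation BCE ", signif(x$best_val_loss, 4), ")\n")
  cat("  pairs: train", nrow(x$split$train), "/ val",
      nrow(x$split$validation), "/ test", nrow(x$split$test), "\n")
  invisible(x)
}

#' @export
coef.patho_fit <- function(object, ...) object$params

#' Node embeddings from a fitted graph model
#'
#' @param object A fitted `patho_fit` with `model = "gcn"`.
#' @return Matrix of 64-wide node embeddings (evaluation mode).
#' @export
node_embeddings <- function(object) {
  stopifnot(inherits(object, "patho_fit"), object$model == "gcn")
  gcn_encode(object$features, object$A_hat, object$params, training = FALSE)
}

#' @export
predict.patho_fit <- function(object, pairs = NULL,
                              type = c("response", "class"), ...) {
  type <- match.arg(type)
  if (is.null(pairs)) pairs <- object$split$test
  ix <- .pair_indices(pairs, object$node_ids)
  if (object$model == "gcn") {
    E <- .gcn_forward(object$features, object$A_hat, object$params,
                      training = FALSE)$E
    p <- decode_pair(E[ix$iv, , drop = FALSE], E[ix$idd, , drop = FALSE],
                     object$params, training = FALSE)
  } else {
    U <- .baseline_input(object$features, ix, object$model)
    p <- .mlp_forward(U, object$params, training = FALSE)$p
  }
  if (type == "class") as.integer(p >= object$control$threshold) else p
}

#' @export
fitted.patho_fit <- function(object, ...) {
  predict(object, pairs = object$split$train)
}

#' @export
residuals.patho_fit <- function(object, ...) {
  object$split$train$label - fitted(object)
}

#' @export
summary.patho_fit <- function(object, pairs = NULL, bootstrap = FALSE, ...) {
  report <- evaluate(object, pairs = pairs, bootstrap = bootstrap)
  out <- list(fit = object, report = report)
  class(out) <- "summary.patho_fit"
  out
}

#' @export
print.summary.patho_fit <- function(x, ...) {
  print(x$fit)
  print(x$report)
  invisible(x)
}

#' @export
plot.patho_fit <- function(x, ...) {
  h <- x$history
  if (!nrow(h)) {
    warning("no training history to plot")
    return(invisible(x))
  }
  graphics::plot(h$epoch, h$train_loss, type = "l", xlab = "epoch",
                 ylab = "binary cross-entropy",
                 ylim = range(c(h$train_loss, h$val_loss)), ...)
  graphics::lines(h$epoch, h$val_loss, lty = 2)
  graphics::abline(v = x$best_epoch, col = "grey60", lty = 3)
  graphics::legend("topright", c("train", "validation"), lty = c(1, 2),
                   bty = "n")
  invisible(x)
}

#' Evaluate a fitted model on a pair set
#'
#' Computes evaluation-mode probabilities for the pairs (the test partition
#' by default), thresholds them at the control threshold, and returns the
#' full report: confusion matrix, balanced accuracy, sensitivity,
#' specificity, PPV, NPV, Wilson confidence interval and exact binomial
#' p-value (plus a bootstrap interval on request).
#'
#' @param fit A `patho_fit`.
#' @param pairs Pair table; defaults to the fit's test partition.
#' @param bootstrap Also compute the bootstrap CI.
#' @return A `patho_eval` report.
#' @export
evaluate <- function(fit, pairs = NULL, bootstrap = FALSE) {
  stopifnot(inherits(fit, "patho_fit"))
  if (is.null(pairs)) pairs <- fit$split$test
  if (!nrow(pairs)) stop("empty pair list", call. = FALSE)
  p <- predict(fit, pairs = pairs)
  eval_report(p, pairs$label, threshold = fit$control$threshold,
              bootstrap = bootstrap, seed = fit$control$seed)
}
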