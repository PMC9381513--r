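#' Build neighborhood documents for topic modeling
#'
#' For every cell (the anchor), collects its `n_neighbors` nearest cells of
#' any type (self excluded) and turns them into a bag of word tokens: each
#' neighbor contributes its lineage label, plus one `label:marker+` token
#' for every functional marker on which that neighbor is gated positive.
#' With `n_neighbors = 0` the document holds the anchor's own tokens, by
#' convention.
#'
#' @param table a [cell_table()].
#' @param typed a `cell_type_call` or label vector.
#' @param gates named list of per-cell positivity: `marker -> logical`
#'   vector aligned with `table` (e.g. from [gmm_gate()] on functional
#'   markers such as CD39, CD73, PD-L1, HIF1a, CD163, CD11b). May be empty.
#' @param n_neighbors neighborhood size (default 10).
#' @return object of class `neighborhood_documents`: list with `counts`
#'   (documents x vocabulary integer matrix), `vocabulary`, `anchor_id`.
#' @export
build_documents <- function(table, typed, gates = list(), n_neighbors = 10L) {
  labels <- typed_labels(typed)
  n <- n_cells(table)
  if (n_neighbors > 0L && n < n_neighbors + 1L) {
    stop("build_documents: need more cells than n_neighbors")
  }
  for (mk in names(gates)) {
    stopifnot(length(gates[[mk]]) == n)
  }
  # per-cell token list (each cell's own tokens)
  cell_tokens <- lapply(seq_len(n), function(i) {
    tk <- labels[i]
    for (mk in names(gates)) {
      if (gates[[mk]][i]) tk <- c(tk, paste0(labels[i], ":", mk, "+"))
    }
    tk
  })
  if (n_neighbors == 0L) {
    members <- as.list(seq_len(n))
  } else {
    nn <- knn_of_type(table, labels, "All", "All", n_neighbors)
    members <- lapply(seq_len(n), function(i) nn$nn_row[i, ])
  }
  vocab <- sort(unique(unlist(cell_tokens)))
  counts <- matrix(0L, nrow = n, ncol = length(vocab),
                   dimnames = list(table$data$cell_id, vocab))
  for (i in seq_len(n)) {
    tk <- unlist(cell_tokens[members[[i]]])
    tt <- table(factor(tk, levels = vocab))
    counts[i, ] <- as.integer(tt)
  }
  structure(list(counts = counts, vocabulary = vocab,
                 anchor_id = table$data$cell_id),
            class = "neighborhood_documents")
}

#' Fit an LDA neighborhood model
#'
#' Latent Dirichlet allocation over neighborhood documents by batch
#' variational Bayes (the standard mean-field coordinate ascent on the
#' smoothed model, with per-document variational Dirichlet parameters
#' `gamma` and global topic-word parameters `lambda`). Fully deterministic
#' under a fixed seed, and identical documents receive identical topic
#' mixtures.
#'
#' @param documents a [build_documents()] result.
#' @param n_topics number of topics (default 12).
#' @param seed integer seed (for the topic-word initialization).
#' @param alpha,beta Dirichlet hyperparameters (document-topic and
#'   topic-word).
#' @param n_iter maximum variational EM iterations.
#' @param tol relative change in the variational bound per token at which
#'   iteration stops.
#' @return object of class `neighborhood_model`: list with `topics`
#'   (n_topics x vocabulary probability matrix, rows sum to 1),
#'   `doc_topics` (documents x n_topics probability matrix, rows sum to 1),
#'   `n_topics`, `vocabulary`, `anchor_id`, `seed`.
#' @export
fit_lda <- function(documents, n_topics = 12L, seed = 1L,
                    alpha = 1, beta = 0.1, n_iter = 200L, tol = 1e-6) {
  counts <- documents$counts
  if (nrow(counts) < n_topics) {
    stop("fit_lda: need at least n_topics documents")
  }
  if (ncol(counts) < 2L) {
    warning("fit_lda: single-word vocabulary; model is degenerate with one effective topic")
  }
  res <- lda_vb(counts, n_topics = as.integer(n_topics), seed = seed,
                alpha = alpha, eta = beta, n_iter = n_iter, tol = tol)
  phi <- res$lambda / rowSums(res$lambda)
  theta <- res$gamma / rowSums(res$gamma)
  dimnames(phi) <- list(paste0("topic", seq_len(n_topics)),
                        documents$vocabulary)
  dimnames(theta) <- list(documents$anchor_id,
                          paste0("topic", seq_len(n_topics)))
  structure(
    list(topics = phi, doc_topics = theta, n_topics = as.integer(n_topics),
         vocabulary = documents$vocabulary, anchor_id = documents$anchor_id,
         seed = as.integer(seed)),
    class = "neighborhood_model"
  )
}

# Batch variational Bayes for smoothed LDA (mean-field coordinate ascent
# in the matrix form of Hoffman et al.'s batch update). C is the D x V
# count matrix; returns the variational Dirichlet parameters gamma (D x K)
# and lambda (K x V).
lda_vb <- function(C, n_topics, seed = 1L, alpha = 1, eta = 0.1,
                   n_iter = 200L, inner_iter = 30L, tol = 1e-6) {
  D <- nrow(C)
  V <- ncol(C)
  K <- n_topics
  set.seed(seed)
  lambda <- matrix(stats::rgamma(K * V, 100, 100), K, V)
  gamma <- matrix(alpha + sum(C) / (D * K), D, K)
  n_tokens <- sum(C)
  last <- -Inf
  for (it in seq_len(n_iter)) {
    expElogbeta <- exp(digamma(lambda) - digamma(rowSums(lambda)))
    for (jt in seq_len(inner_iter)) {
      expElogtheta <- exp(digamma(gamma) - digamma(rowSums(gamma)))
      phinorm <- expElogtheta %*% expElogbeta + 1e-100
      gamma_new <- alpha +
        expElogtheta * ((C / phinorm) %*% t(expElogbeta))
      delta <- mean(abs(gamma_new - gamma))
      gamma <- gamma_new
      if (delta < 1e-4) break
    }
    expElogtheta <- exp(digamma(gamma) - digamma(rowSums(gamma)))
    phinorm <- expElogtheta %*% expElogbeta + 1e-100
    lambda <- eta + expElogbeta * (t(expElogtheta) %*% (C / phinorm))
    bound <- sum(C * log(phinorm)) / n_tokens
    if (is.finite(last) && abs(bound - last) < tol * abs(last + 1e-12)) break
    last <- bound
  }
  list(gamma = gamma, lambda = lambda, n_iter = it)
}

#' @export
print.neighborhood_model <- function(x, ...) {
  cat(sprintf("neighborhood_model: %d topics, %d documents, %d words\n",
              x$n_topics, nrow(x$doc_topics), length(x$vocabulary)))
  invisible(x)
}

#' Map topics back onto cells
#'
#' Assigns each cell its dominant topic (argmax of its document-topic row,
#' ties resolved to the lowest topic index) and summarizes topic
#' composition per core.
#'
#' @param model a [fit_lda()] result.
#' @param table the [cell_table()] the documents were built from.
#' @return list with `cells` (data.frame: cell_id, topic) and `composition`
#'   (data.frame: core_id, topic, fraction; fractions sum to 1 per core).
#' @export
map_topics <- function(model, table) {
  stopifnot(identical(model$anchor_id, table$data$cell_id))
  dominant <- max.col(model$doc_topics, ties.method = "first")
  cells <- data.frame(cell_id = table$data$cell_id, topic = dominant,
                      stringsAsFactors = FALSE)
  comp <- do.call(rbind, lapply(split(dominant, table$data$core_id),
                                function(tp) {
    tab <- table(factor(tp, levels = seq_len(model$n_topics)))
    data.frame(topic = as.integer(names(tab)),
               fraction = as.numeric(tab) / length(tp))
  }))
  comp <- data.frame(
    core_id = rep(names(split(dominant, table$data$core_id)),
                  each = model$n_topics),
    comp, row.names = NULL, stringsAsFactors = FALSE
  )
  list(cells = cells, composition = comp)
}
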