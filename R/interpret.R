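#' Cosine similarity matrix of embedding rows
#'
#' @param X matrix with one embedding per row (row names preserved).
#' @return Symmetric matrix with unit diagonal, entries in `[-1, 1]`.
#' @export
cosine_similarity_matrix <- function(X) {
  X <- as.matrix(X)
  nrm <- sqrt(rowSums(X^2))
  zero <- which(nrm == 0)
  if (length(zero) > 0) {
    nm <- rownames(X)[zero[1]] %||% as.character(zero[1])
    stop(sprintf("zero-norm embedding row: %s", nm))
  }
  C <- tcrossprod(X / nrm)
  C[C > 1] <- 1
  C[C < -1] <- -1
  diag(C) <- 1
  C
}

.offdiag_mean <- function(C) {
  if (nrow(C) < 2) return(NA_real_)
  mean(C[row(C) != col(C)])
}

#' Compare embedding similarity of top- vs bottom-ranked candidates
#'
#' For a query disease, selects the k highest- and k lowest-scored candidate
#' snoRNAs (candidates have no known training association with the disease)
#' and returns the two cosine-similarity matrices of their final embeddings
#' together with the off-diagonal means. In a model that has captured
#' snoRNA-level similarity structure, the top group is expected to be more
#' internally similar than the bottom group.
#'
#' @param model an [train_model()] result holding a `table`.
#' @param disease disease name.
#' @param k group size (default 10); needs at least `2k` candidates.
#' @return List with `top`, `bottom` (cosine matrices), `top_snornas`,
#'   `bottom_snornas`, and `summary` (off-diagonal means).
#' @export
top_bottom_similarity <- function(model, disease, k = 10L) {
  table <- model$table
  if (is.null(table))
    stop("model carries no association_table; pass table= to train_model()")
  ranked <- rank_candidates(model, disease, top_n = table$N)
  if (nrow(ranked) < 2 * k)
    stop(sprintf("need at least %d candidates, have %d", 2 * k, nrow(ranked)))
  top_names <- head(ranked$snorna, k)
  bottom_names <- tail(ranked$snorna, k)
  emb <- model$e_r
  rownames(emb) <- table$snornas
  top <- cosine_similarity_matrix(emb[top_names, , drop = FALSE])
  bottom <- cosine_similarity_matrix(emb[bottom_names, , drop = FALSE])
  list(top = top, bottom = bottom,
       top_snornas = top_names, bottom_snornas = bottom_names,
       summary = list(top_mean = .offdiag_mean(top),
                      bottom_mean = .offdiag_mean(bottom)))
}

#' Export final embeddings as TSV
#'
#' One row per node: name, family (`snorna`/`disease`), optional group
#' label, then the embedding coordinates. Values are written with full
#' precision so a reload reproduces the matrices exactly.
#'
#' @param model an [train_model()] result holding a `table`.
#' @param path output path.
#' @param nodes optional character vector of node names to export (default
#'   all snoRNAs and diseases).
#' @param groups optional named vector of group labels.
#' @return `path`, invisibly.
#' @export
export_embeddings <- function(model, path, nodes = NULL, groups = NULL) {
  table <- model$table
  if (is.null(table))
    stop("model carries no association_table; pass table= to train_model()")
  L <- ncol(model$e_r)
  all_names <- c(table$snornas, table$diseases)
  all_family <- c(rep("snorna", table$N), rep("disease", table$M))
  emb <- rbind(model$e_r, model$e_d)
  rownames(emb) <- all_names
  keep <- if (is.null(nodes)) seq_along(all_names)
          else match(nodes, all_names)
  if (anyNA(keep)) stop(sprintf("unknown node(s): %s",
                                paste(nodes[is.na(keep)], collapse = ", ")))
  header <- c("node", "family", "group", paste0("e", seq_len(L)))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(header, collapse = "\t"), con)
  for (i in keep) {
    g <- if (!is.null(groups) && all_names[i] %in% names(groups))
      as.character(groups[[all_names[i]]]) else "NA"
    writeLines(paste(c(all_names[i], all_family[i], g,
                       sprintf("%.17g", emb[i, ])), collapse = "\t"), con)
  }
  invisible(path)
}

#' Read embeddings written by [export_embeddings()]
#'
#' @param path TSV path.
#' @return List with `meta` (node, family, group) and the embedding `matrix`
#'   (row names = node names).
#' @export
read_embeddings <- function(path) {
  df <- read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
                   colClasses = "character")
  meta <- df[, 1:3, drop = FALSE]
  if (ncol(df) > 3) {
    m <- as.matrix(df[, -(1:3), drop = FALSE])
    storage.mode(m) <- "double"
  } else {
    m <- matrix(numeric(0), nrow(df), 0)
  }
  rownames(m) <- df$node
  list(meta = meta, matrix = m)
}
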