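# Checkpoints are plain-text directories: every parameter matrix as a
# full-precision TSV, the configs and training pair indices as JSON, and the
# association table as an edge list. Final embeddings are recomputed from the
# parameters on load (the forward pass is deterministic), so the round trip
# is exact.

.write_matrix_tsv <- function(m, path) {
  m <- as.matrix(m)
  lines <- apply(m, 1, function(row)
    paste(sprintf("%.17g", row), collapse = "\t"))
  writeLines(lines, path)
}

.read_matrix_tsv <- function(path) {
  m <- as.matrix(read.table(path, sep = "\t", header = FALSE,
                            colClasses = "numeric"))
  dimnames(m) <- NULL
  m
}

#' Save a trained model as a plain-text checkpoint directory
#'
#' @param model an [train_model()] result holding a `table`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
save_checkpoint <- function(model, dir) {
  if (is.null(model$table))
    stop("model carries no association_table; pass table= to train_model()")
  dir.create(file.path(dir, "params"), recursive = TRUE, showWarnings = FALSE)
  for (nm in names(model$params)) {
    p <- model$params[[nm]]
    .write_matrix_tsv(if (is.matrix(p)) p else matrix(p, nrow = 1),
                      file.path(dir, "params", paste0(nm, ".tsv")))
  }
  write_associations(model$table, file.path(dir, "associations.tsv"))
  # recover which table pairs form the training graph
  key_graph <- paste(model$graph$edges$snorna_idx, model$graph$edges$disease_idx)
  key_tab <- paste(model$table$pairs$snorna_idx, model$table$pairs$disease_idx)
  train_idx <- which(key_tab %in% key_graph)
  jsonlite::write_json(
    list(model_config = unclass(model$config),
         train_config = unclass(model$tconfig),
         train_idx = train_idx,
         vector_params = names(model$params)[!vapply(model$params, is.matrix,
                                                     logical(1))]),
    file.path(dir, "config.json"), auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}

#' Load a checkpoint written by [save_checkpoint()]
#'
#' Rebuilds the table, training graph and parameters, and reruns the forward
#' pass to restore final embeddings and the subgraph assignment.
#'
#' @param dir checkpoint directory.
#' @return An object of class `sda_model`.
#' @export
load_checkpoint <- function(dir) {
  cfg <- jsonlite::read_json(file.path(dir, "config.json"),
                             simplifyVector = TRUE)
  mc <- do.call(model_config, cfg$model_config[
    setdiff(names(cfg$model_config), character(0))])
  tc_fields <- cfg$train_config
  tc_fields$batch_size <- cfg$train_config$batch_size
  tc <- do.call(train_config, tc_fields)
  table <- load_associations(file.path(dir, "associations.tsv"))
  graph <- build_graph(table, as.integer(cfg$train_idx))
  files <- list.files(file.path(dir, "params"), pattern = "\\.tsv$")
  params <- list()
  for (f in files) {
    nm <- sub("\\.tsv$", "", f)
    m <- .read_matrix_tsv(file.path(dir, "params", f))
    params[[nm]] <- if (nm %in% cfg$vector_params) as.vector(m) else m
  }
  params <- params[c("E_r", "E_d", "W1", "b1", "W2", "b2", "W3", "b3")]
  fw <- .forward(params, graph, mc)
  structure(
    list(params = params, e_r = fw$e_r, e_d = fw$e_d,
         assignment = fw$assignment,
         history = data.frame(epoch = integer(0), loss = numeric(0),
                              val_auc = numeric(0)),
         graph = graph, config = mc, tconfig = tc, table = table),
    class = "sda_model")
}
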