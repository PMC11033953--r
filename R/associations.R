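#' Build an association table from snoRNA and disease name vectors
#'
#' The association table is the package's central data object: the list of
#' known snoRNA-disease pairs together with bidirectional name/index maps.
#' Duplicate pairs are dropped (with a message); indices are assigned in
#' first-appearance order, so the same input always yields the same maps.
#'
#' @param snorna character vector of snoRNA names.
#' @param disease character vector of disease names, same length.
#' @return An object of class `association_table` with elements `pairs`
#'   (data frame: `snorna`, `disease`, `snorna_idx`, `disease_idx`),
#'   `snornas`, `diseases` (name vectors in index order), and counts `N`, `M`.
#' @examples
#' tab <- association_table(c("s1", "s1", "s2"), c("d1", "d1", "d2"))
#' tab$N # 2
#' @export
association_table <- function(snorna, disease) {
  stopifnot(length(snorna) == length(disease), length(snorna) >= 1)
  snorna <- as.character(snorna)
  disease <- as.character(disease)
  if (anyNA(snorna) || anyNA(disease) || any(snorna == "") || any(disease == ""))
    stop("association names must be non-empty and non-missing")
  key <- paste0(snorna, "\r", disease)
  dup <- duplicated(key)
  if (any(dup))
    message(sprintf("dropped %d duplicate association pair(s)", sum(dup)))
  snorna <- snorna[!dup]
  disease <- disease[!dup]
  snornas <- unique(snorna)
  diseases <- unique(disease)
  pairs <- data.frame(
    snorna = snorna,
    disease = disease,
    snorna_idx = match(snorna, snornas),
    disease_idx = match(disease, diseases),
    stringsAsFactors = FALSE
  )
  structure(
    list(pairs = pairs, snornas = snornas, diseases = diseases,
         N = length(snornas), M = length(diseases)),
    class = "association_table"
  )
}

#' @export
print.association_table <- function(x, ...) {
  cat(sprintf("association_table: %d snoRNAs x %d diseases, %d pairs\n",
              x$N, x$M, nrow(x$pairs)))
  invisible(x)
}

#' Read a snoRNA-disease edge list from TSV or CSV
#'
#' Expects at least two columns per row: snoRNA name, disease name; extra
#' columns are ignored. A header line is detected when the first field is
#' "snorna" or the second is "disease" (case-insensitive); set `header`
#' explicitly to override. Duplicate pairs are dropped with a message.
#'
#' @param path path to the file.
#' @param dialect `"tsv"` (default) or `"csv"`.
#' @param header `"auto"` (default), `TRUE` or `FALSE`.
#' @return An [association_table()].
#' @export
load_associations <- function(path, dialect = c("tsv", "csv"), header = "auto") {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  sep <- if (dialect == "tsv") "\t" else ","
  lines <- readLines(path, warn = FALSE)
  lines_keep <- which(nzchar(trimws(lines)))
  if (length(lines_keep) == 0) stop(sprintf("empty association file: %s", path))
  fields <- strsplit(lines[lines_keep], sep, fixed = TRUE)
  first <- trimws(fields[[1]])
  has_header <- if (identical(header, "auto")) {
    length(first) >= 2 &&
      (tolower(first[1]) %in% c("snorna", "snornas") ||
         tolower(first[2]) %in% c("disease", "diseases"))
  } else {
    isTRUE(header)
  }
  if (has_header) {
    fields <- fields[-1]
    lines_keep <- lines_keep[-1]
  }
  if (length(fields) == 0) stop(sprintf("no data rows in %s", path))
  nf <- lengths(fields)
  bad <- which(nf < 2)
  if (length(bad) > 0)
    stop(sprintf("malformed row at line %d of %s: need >= 2 columns",
                 lines_keep[bad[1]], path))
  snorna <- trimws(vapply(fields, `[[`, "", 1))
  disease <- trimws(vapply(fields, `[[`, "", 2))
  blank <- which(snorna == "" | disease == "")
  if (length(blank) > 0)
    stop(sprintf("malformed row at line %d of %s: empty name field",
                 lines_keep[blank[1]], path))
  association_table(snorna, disease)
}

#' Write an association table as an edge list
#'
#' @param table an [association_table()].
#' @param path output path.
#' @param dialect `"tsv"` or `"csv"`.
#' @return `path`, invisibly.
#' @export
write_associations <- function(table, path, dialect = c("tsv", "csv")) {
  dialect <- match.arg(dialect)
  stopifnot(inherits(table, "association_table"))
  sep <- if (dialect == "tsv") "\t" else ","
  write.table(table$pairs[, c("snorna", "disease")], path,
              sep = sep, quote = FALSE, row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Randomly split association pairs into train and test sets
#'
#' Draws a uniform random permutation of the pair indices under `seed`; the
#' first `round(ratio * n)` pairs form the training set. With the benchmark
#' curation of 1095 pairs and `ratio = 0.8` this yields 876 train / 219 test.
#'
#' @param table an [association_table()].
#' @param ratio training fraction in (0, 1); default 0.8.
#' @param seed integer seed.
#' @return An object of class `split_plan`: `train` and `test` pair-index
#'   vectors, `ratio`, `seed`.
#' @export
split_pairs <- function(table, ratio = 0.8, seed = 1L) {
  stopifnot(inherits(table, "association_table"))
  if (!(ratio > 0 && ratio < 1)) stop("ratio must lie strictly in (0, 1)")
  n <- nrow(table$pairs)
  n_train <- round(ratio * n)
  if (n_train < 1 || n_train >= n)
    stop(sprintf("ratio %g yields an empty partition for %d pairs", ratio, n))
  perm <- withr::with_seed(seed, sample.int(n))
  structure(
    list(train = sort(perm[seq_len(n_train)]),
         test = sort(perm[-seq_len(n_train)]),
         ratio = ratio, seed = as.integer(seed)),
    class = "split_plan"
  )
}

#' Partition association pairs into k cross-validation folds
#'
#' Fold sizes differ by at most one; folds are disjoint and cover all pairs.
#'
#' @param table an [association_table()].
#' @param k number of folds (>= 2, <= number of pairs).
#' @param seed integer seed.
#' @return An object of class `fold_plan` with a list `folds` of pair-index
#'   vectors and the `seed`.
#' @export
make_folds <- function(table, k = 5L, seed = 1L) {
  stopifnot(inherits(table, "association_table"))
  n <- nrow(table$pairs)
  k <- as.integer(k)
  if (k < 2) stop("k must be >= 2")
  if (k > n) stop(sprintf("k = %d exceeds the number of pairs (%d)", k, n))
  perm <- withr::with_seed(seed, sample.int(n))
  sizes <- rep(n %/% k, k)
  extra <- n %% k
  if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  ends <- cumsum(sizes)
  starts <- c(1L, head(ends, -1L) + 1L)
  folds <- lapply(seq_len(k), function(i) sort(perm[starts[i]:ends[i]]))
  structure(list(folds = folds, k = k, seed = as.integer(seed)),
            class = "fold_plan")
}

#' Inject false-positive noise pairs into a train/test split
#'
#' Adds `round(fraction * n_pairs)` uniformly sampled non-associated
#' (snoRNA, disease) cells as spurious positives to the chosen partition,
#' emulating label noise at 1% or 5% of the full association count. The
#' injected pairs are returned so their predictions can be audited afterwards
#' (they are known false positives).
#'
#' @param table an [association_table()].
#' @param fraction noise fraction of the total pair count (e.g. 0.01, 0.05).
#' @param target `"train"` or `"test"`: which partition receives the noise.
#' @param plan a [split_pairs()] plan for `table`.
#' @param seed integer seed.
#' @return An object of class `noise_plan`: `table` (augmented with the
#'   injected pairs), `plan` (indices into the augmented table), `injected`
#'   (row indices of the injected pairs), `target`, `fraction`.
#' @export
inject_noise <- function(table, fraction, target = c("train", "test"),
                         plan, seed = 1L) {
  target <- match.arg(target)
  stopifnot(inherits(table, "association_table"), inherits(plan, "split_plan"))
  if (fraction < 0) stop("fraction must be non-negative")
  n <- nrow(table$pairs)
  n_inject <- round(fraction * n)
  if (n_inject == 0) {
    return(structure(list(table = table, plan = plan, injected = integer(0),
                          target = target, fraction = fraction),
                     class = "noise_plan"))
  }
  occupied <- (table$pairs$disease_idx - 1L) * table$N + table$pairs$snorna_idx
  free <- setdiff(seq_len(table$N * table$M), occupied)
  if (length(free) < n_inject)
    stop(sprintf("only %d non-associated cells available, need %d",
                 length(free), n_inject))
  cells <- withr::with_seed(seed, sample(free, n_inject))
  r_idx <- (cells - 1L) %% table$N + 1L
  d_idx <- (cells - 1L) %/% table$N + 1L
  extra <- data.frame(
    snorna = table$snornas[r_idx],
    disease = table$diseases[d_idx],
    snorna_idx = r_idx,
    disease_idx = d_idx,
    stringsAsFactors = FALSE
  )
  table_aug <- table
  table_aug$pairs <- rbind(table$pairs, extra)
  rownames(table_aug$pairs) <- NULL
  new_idx <- n + seq_len(n_inject)
  plan_aug <- plan
  if (target == "train") plan_aug$train <- c(plan$train, new_idx)
  else plan_aug$test <- c(plan$test, new_idx)
  structure(list(table = table_aug, plan = plan_aug, injected = new_idx,
                 target = target, fraction = fraction),
            class = "noise_plan")
}
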