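#' Read a contact-pair list from delimited text
#'
#' Ingests the pair lists produced by evolutionary-coupling pipelines. Two
#' dialects are auto-detected from the column count: minimal
#' `(res_i, res_j, score)` and chain-tagged
#' `(res_i, chain_i, res_j, chain_j, score)`. The delimiter (whitespace,
#' comma, or tab) and an optional header row are auto-detected. Malformed
#' lines are skipped with a warning naming their line numbers.
#'
#' @param path file path.
#' @return A contacts [tibble::tibble()] with columns `res_i`, `res_j`,
#'   `score`, `chain_i`, `chain_j`, in file order.
#' @export
read_contacts <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  lines_keep <- which(nzchar(trimws(lines)) & !startsWith(trimws(lines), "#"))
  if (length(lines_keep) == 0) {
    warning("empty contact file: ", path)
    return(tibble::tibble(res_i = integer(), res_j = integer(),
                          score = numeric(), chain_i = character(),
                          chain_j = character()))
  }
  split_line <- function(x) {
    x <- gsub(",", " ", x, fixed = TRUE)
    strsplit(trimws(x), "[ \t]+")[[1]]
  }
  toks <- lapply(lines[lines_keep], split_line)
  ncols <- vapply(toks, length, 1L)
  layout <- stats::median(ncols)
  if (!layout %in% c(3, 5)) {
    stop(sprintf(
      "unknown contact-file layout: detected %d columns (%s); expected 3 (i, j, score) or 5 (i, chain_i, j, chain_j, score)",
      layout, paste(utils::head(toks[[1]], 6), collapse = " ")))
  }
  numish <- function(x) !is.na(suppressWarnings(as.numeric(x)))
  start <- 1L
  if (layout == 3 && !all(numish(toks[[1]]))) start <- 2L
  if (layout == 5 && !(numish(toks[[1]][1]) && numish(toks[[1]][3]) &&
                       numish(toks[[1]][5]))) start <- 2L
  rows <- vector("list", length(toks))
  bad <- integer()
  for (k in seq(start, length(toks))) {
    tk <- toks[[k]]
    ok <- length(tk) == layout &&
      (if (layout == 3) all(numish(tk)) else
        numish(tk[1]) && numish(tk[3]) && numish(tk[5]))
    if (!ok) { bad <- c(bad, lines_keep[k]); next }
    rows[[k]] <- if (layout == 3) {
      list(as.integer(tk[1]), as.integer(tk[2]), as.numeric(tk[3]), "A", "A")
    } else {
      list(as.integer(tk[1]), as.integer(tk[3]), as.numeric(tk[5]),
           tk[2], tk[4])
    }
  }
  if (length(bad)) {
    warning(sprintf("skipped %d malformed line(s): %s", length(bad),
                    paste(bad, collapse = ", ")))
  }
  rows <- rows[!vapply(rows, is.null, TRUE)]
  if (length(rows) == 0) {
    warning("no parseable contact records in: ", path)
    return(tibble::tibble(res_i = integer(), res_j = integer(),
                          score = numeric(), chain_i = character(),
                          chain_j = character()))
  }
  tibble::tibble(
    res_i = vapply(rows, function(r) r[[1]], 1L),
    res_j = vapply(rows, function(r) r[[2]], 1L),
    score = vapply(rows, function(r) r[[3]], 1),
    chain_i = vapply(rows, function(r) r[[4]], ""),
    chain_j = vapply(rows, function(r) r[[5]], "")
  )
}

#' Write a contact-pair list as delimited text
#'
#' Same-chain-only lists are written in the minimal 3-column dialect;
#' lists containing inter-chain pairs in the tagged 5-column dialect.
#'
#' @param pairs a contacts tibble (see [read_contacts()]).
#' @param path output file path.
#' @param header write a header row?
#' @return `path`, invisibly.
#' @export
write_contacts <- function(pairs, path, header = TRUE) {
  tagged <- any(pairs$chain_i != pairs$chain_j) ||
    any(pairs$chain_i != "A")
  if (tagged) {
    df <- data.frame(res_i = pairs$res_i, chain_i = pairs$chain_i,
                     res_j = pairs$res_j, chain_j = pairs$chain_j,
                     score = pairs$score)
  } else {
    df <- data.frame(res_i = pairs$res_i, res_j = pairs$res_j,
                     score = pairs$score)
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = header)
  invisible(path)
}

#' Select the top-N contact pairs by score
#'
#' Pairs are ranked by score descending with ties broken by
#' `(res_i, res_j)` ascending. Same-chain pairs closer in sequence than
#' `min_separation` are removed before truncation (covariance pipelines
#' exclude near-diagonal pairs, which are trivially proximal).
#'
#' @param pairs a contacts tibble.
#' @param n number of pairs to keep (the analysis default is 90 same-chain
#'   pairs; 6 is typical for an inter-chain set).
#' @param min_separation minimum |res_i - res_j| for same-chain pairs.
#' @param chains `"all"`, `"intra"` (same-chain only) or `"inter"`
#'   (cross-chain only).
#' @return A contacts tibble with at most `n` rows, scores non-increasing.
#' @export
top_n_contacts <- function(pairs, n = 90, min_separation = 5,
                           chains = c("all", "intra", "inter")) {
  chains <- match.arg(chains)
  if (n < 1) stop("n must be >= 1")
  same <- pairs$chain_i == pairs$chain_j
  keep <- !(same & abs(pairs$res_i - pairs$res_j) < min_separation)
  if (chains == "intra") keep <- keep & same
  if (chains == "inter") keep <- keep & !same
  out <- pairs[keep, ]
  out <- out[order(-out$score, out$res_i, out$res_j), ]
  utils::head(out, n)
}

#' Score contact-pair satisfaction against a structural model
#'
#' For every pair whose residues are both present in the supplied models, the
#' CA-CA Euclidean distance is computed (across chains when the tags differ)
#' and compared to `threshold`. The headline statistic is the fraction of
#' resolvable pairs satisfied and their mean distance. Pairs referencing
#' residues absent from the models (e.g. unbuilt loops) are reported as
#' `unresolved`, never silently dropped and never counted as violations.
#'
#' @param models a [backbone_model()] (treated as chain "A") or a named list
#'   of models keyed by chain tag.
#' @param pairs a contacts tibble.
#' @param threshold satisfaction distance in Angstrom (default 15, the
#'   standard model-checking threshold at medium resolution).
#' @return An object of class `satisfaction_report`: list with `n_pairs`
#'   (resolvable pairs), `n_satisfied`, `fraction_satisfied`,
#'   `mean_distance`, `threshold`, `distances` (per-pair tibble),
#'   `violations` and `unresolved` tibbles.
#' @export
satisfaction <- function(models, pairs, threshold = 15) {
  if (threshold <= 0) stop("threshold must be positive")
  if (inherits(models, "backbone_model")) models <- list(A = models)
  d <- rep(NA_real_, nrow(pairs))
  for (k in seq_len(nrow(pairs))) {
    mi <- models[[pairs$chain_i[k]]]
    mj <- models[[pairs$chain_j[k]]]
    if (is.null(mi) || is.null(mj)) next
    a <- ca_at(mi, pairs$res_i[k])
    b <- ca_at(mj, pairs$res_j[k])
    if (anyNA(a) || anyNA(b)) next
    d[k] <- sqrt(sum((a - b)^2))
  }
  resolvable <- !is.na(d)
  if (!any(resolvable)) {
    stop("no resolvable pairs: satisfaction fraction is undefined")
  }
  dist_tbl <- tibble::tibble(
    res_i = pairs$res_i, res_j = pairs$res_j,
    chain_i = pairs$chain_i, chain_j = pairs$chain_j,
    score = pairs$score, distance = d,
    satisfied = !is.na(d) & d <= threshold
  )
  res <- dist_tbl[resolvable, ]
  structure(list(
    n_pairs = nrow(res),
    n_satisfied = sum(res$satisfied),
    fraction_satisfied = mean(res$satisfied),
    mean_distance = mean(res$distance),
    threshold = threshold,
    distances = dist_tbl,
    violations = res[!res$satisfied, ],
    unresolved = dist_tbl[!resolvable, ]
  ), class = "satisfaction_report")
}

#' @export
print.satisfaction_report <- function(x, ...) {
  cat("<satisfaction_report>\n")
  cat(sprintf("  %d/%d resolvable pairs within %.1f A (%.1f%%), mean CA-CA %.2f A\n",
              x$n_satisfied, x$n_pairs, x$threshold,
              100 * x$fraction_satisfied, x$mean_distance))
  if (nrow(x$unresolved) > 0) {
    cat(sprintf("  %d pair(s) unresolved (residues absent from model)\n",
                nrow(x$unresolved)))
  }
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Per-pair detail of a satisfaction report
#' @param x a `satisfaction_report`.
#' @param ... unused.
#' @return Tibble with one row per input pair: distances, satisfied flag
#'   (`NA` distance marks unresolved pairs).
#' @export
tidy.satisfaction_report <- function(x, ...) x$distances

#' One-row summary of a satisfaction report
#' @param x a `satisfaction_report`.
#' @param ... unused.
#' @return One-row tibble: `n_pairs`, `n_satisfied`, `fraction_satisfied`,
#'   `mean_distance`, `threshold`, `n_unresolved`.
#' @export
glance.satisfaction_report <- function(x, ...) {
  tibble::tibble(n_pairs = x$n_pairs, n_satisfied = x$n_satisfied,
                 fraction_satisfied = x$fraction_satisfied,
                 mean_distance = x$mean_distance, threshold = x$threshold,
                 n_unresolved = nrow(x$unresolved))
}

#' Write a satisfaction report as JSON
#' @param report a `satisfaction_report`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_report_json <- function(report, path) {
  jsonlite::write_json(list(
    n_pairs = report$n_pairs,
    n_satisfied = report$n_satisfied,
    fraction_satisfied = report$fraction_satisfied,
    mean_distance = report$mean_distance,
    threshold = report$threshold,
    violations = report$violations,
    unresolved = report$unresolved[, c("res_i", "res_j", "chain_i", "chain_j")]
  ), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
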