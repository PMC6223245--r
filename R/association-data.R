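# ---- internal helpers for labelled matrices ----------------------------

# A labelled adjacency/score matrix is a base matrix with complete, unique
# dimnames: rows = microbes, columns = diseases.
assert_labelled_matrix <- function(x, what = "matrix") {
  if (!is.matrix(x) || !is.numeric(x))
    stop(what, " must be a numeric matrix", call. = FALSE)
  if (is.null(rownames(x)) || is.null(colnames(x)))
    stop(what, " must have row and column labels", call. = FALSE)
  if (anyDuplicated(rownames(x)) || anyDuplicated(colnames(x)))
    stop(what, " has duplicated labels", call. = FALSE)
  invisible(x)
}

assert_binary <- function(Y, what = "adjacency matrix") {
  if (!all(Y %in% c(0, 1)))
    stop(what, " must be binary (0/1)", call. = FALSE)
  invisible(Y)
}

same_labels <- function(a, b) {
  identical(rownames(a), rownames(b)) && identical(colnames(a), colnames(b))
}

#' Read a microbe-disease association table
#'
#' Reads a delimited text file of known associations, one record per line:
#' `microbe<delim>disease[<delim>evidence]`. Records are kept in file order
#' and duplicates are preserved; deduplication happens in
#' [build_adjacency()].
#'
#' @param path Path to the association file.
#' @param delimiter Field delimiter (default tab).
#' @param header Logical; if `TRUE` the first non-comment line is skipped.
#' @param comment_char Lines starting with this character are ignored.
#' @return A data frame of class `association_table` with columns
#'   `microbe`, `disease`, `evidence` (`NA` when absent). Labels are
#'   whitespace-trimmed, compared case-sensitively.
#' @seealso [build_adjacency()], [write_association_table()]
#' @export
read_association_table <- function(path, delimiter = "\t", header = FALSE,
                                   comment_char = "#") {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  keep <- !startsWith(trimws(lines), comment_char) & nzchar(trimws(lines))
  line_no <- which(keep)
  lines <- lines[keep]
  if (header && length(lines)) {
    lines <- lines[-1]
    line_no <- line_no[-1]
  }
  if (!length(lines)) stop("no association records in ", path, call. = FALSE)
  fields <- strsplit(lines, delimiter, fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 2)) {
    bad <- line_no[which(nf < 2)[1]]
    stop("malformed association line ", bad, " in ", path,
         ": expected at least 2 fields", call. = FALSE)
  }
  microbe <- trimws(vapply(fields, `[[`, "", 1))
  disease <- trimws(vapply(fields, `[[`, "", 2))
  evidence <- trimws(vapply(fields, function(f)
    if (length(f) >= 3) f[[3]] else NA_character_, ""))
  if (any(!nzchar(microbe)) || any(!nzchar(disease))) {
    bad <- line_no[which(!nzchar(microbe) | !nzchar(disease))[1]]
    stop("empty label on line ", bad, " in ", path, call. = FALSE)
  }
  association_table(microbe, disease, evidence)
}

#' Construct an association table in memory
#'
#' @param microbe,disease Character vectors of equal length.
#' @param evidence Optional character vector of evidence identifiers.
#' @return An `association_table` data frame.
#' @export
association_table <- function(microbe, disease, evidence = NA_character_) {
  stopifnot(length(microbe) == length(disease))
  out <- data.frame(microbe = trimws(as.character(microbe)),
                    disease = trimws(as.character(disease)),
                    evidence = rep_len(as.character(evidence), length(microbe)),
                    stringsAsFactors = FALSE)
  if (any(!nzchar(out$microbe)) || any(!nzchar(out$disease)))
    stop("labels must be non-empty strings", call. = FALSE)
  class(out) <- c("association_table", "data.frame")
  out
}

#' Write an association table to a delimited file
#'
#' @param table An `association_table`.
#' @param path Output path.
#' @param delimiter Field delimiter.
#' @export
write_association_table <- function(table, path, delimiter = "\t") {
  has_ev <- !is.na(table$evidence)
  lines <- ifelse(has_ev,
                  paste(table$microbe, table$disease, table$evidence,
                        sep = delimiter),
                  paste(table$microbe, table$disease, sep = delimiter))
  writeLines(lines, path)
  invisible(path)
}

#' Build the binary adjacency matrix from an association table
#'
#' Labels are the sorted unique microbe and disease names; `Y[i, j] = 1`
#' iff the pair occurs at least once in the table. Duplicate records
#' (same pair, different evidence) collapse to a single 1; the number of
#' collapsed records is reported via `message()`.
#'
#' @param table An `association_table`.
#' @return A binary matrix with microbe row labels and disease column
#'   labels.
#' @examples
#' tab <- association_table(c("mA", "mA", "mB"), c("d1", "d1", "d2"))
#' Y <- build_adjacency(tab)
#' sum(Y)  # 2 unique pairs
#' @export
build_adjacency <- function(table) {
  if (!nrow(table)) stop("association table is empty", call. = FALSE)
  microbes <- sort(unique(table$microbe))
  diseases <- sort(unique(table$disease))
  Y <- matrix(0, length(microbes), length(diseases),
              dimnames = list(microbes, diseases))
  Y[cbind(match(table$microbe, microbes), match(table$disease, diseases))] <- 1
  n_dup <- nrow(table) - sum(Y)
  if (n_dup > 0)
    message("collapsed ", n_dup, " duplicate association record",
            if (n_dup > 1) "s", " (", nrow(table), " -> ", sum(Y),
            " unique pairs)")
  Y
}

#' Write a labelled score or adjacency matrix as TSV
#'
#' First row holds the disease labels, first column the microbe labels.
#' Values are written with full double precision so a read-back
#' reproduces them to at least 12 significant digits.
#'
#' @param scores Labelled numeric matrix.
#' @param path Output path.
#' @param delimiter Field delimiter (default tab). Labels containing the
#'   delimiter are rejected.
#' @export
write_score_matrix <- function(scores, path, delimiter = "\t") {
  assert_labelled_matrix(scores, "score matrix")
  if (!all(is.finite(scores)))
    stop("score matrix contains non-finite values", call. = FALSE)
  labs <- c(rownames(scores), colnames(scores))
  if (any(grepl(delimiter, labs, fixed = TRUE)))
    stop("matrix labels contain the delimiter; choose another delimiter",
         call. = FALSE)
  body <- apply(scores, 1, function(r)
    paste(format(r, digits = 17, trim = TRUE, scientific = FALSE),
          collapse = delimiter))
  lines <- c(paste(c("", colnames(scores)), collapse = delimiter),
             paste(rownames(scores), body, sep = delimiter))
  writeLines(lines, path)
  invisible(path)
}

#' Read a labelled matrix written by [write_score_matrix()]
#'
#' Also used for external disease-similarity matrices in the same layout
#' (header row and first column of labels).
#'
#' @param path Input path.
#' @param delimiter Field delimiter.
#' @return A labelled numeric matrix.
#' @export
read_score_matrix <- function(path, delimiter = "\t") {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.table(path, sep = delimiter, header = TRUE,
                          row.names = 1, check.names = FALSE,
                          stringsAsFactors = FALSE)
  m <- as.matrix(df)
  storage.mode(m) <- "double"
  assert_labelled_matrix(m, "score matrix")
  m
}

#' Rank candidate microbes for one disease
#'
#' Ranks microbes that are *not* known to be associated with the disease
#' (i.e. `known[i, disease] == 0`) by descending predicted score. Ties
#' are broken by microbe label (lexicographic) for determinism.
#'
#' @param scores Labelled score matrix.
#' @param known Binary adjacency matrix with the same labels.
#' @param disease_label Disease (column) to rank.
#' @param top Number of candidates to return; `Inf` for all.
#' @return A data frame with columns `microbe`, `score`, `rank`.
#' @export
rank_predictions <- function(scores, known, disease_label, top = 10) {
  assert_labelled_matrix(scores, "score matrix")
  assert_labelled_matrix(known, "adjacency matrix")
  if (!same_labels(scores, known))
    stop("score and adjacency matrices must share labels", call. = FALSE)
  if (!disease_label %in% colnames(scores))
    stop("unknown disease label: ", disease_label, call. = FALSE)
  cand <- rownames(scores)[known[, disease_label] == 0]
  s <- scores[cand, disease_label]
  ord <- order(-s, cand)
  n <- min(top, length(cand))
  data.frame(microbe = cand[ord][seq_len(n)],
             score = unname(s[ord][seq_len(n)]),
             rank = seq_len(n),
             stringsAsFactors = FALSE)
}
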