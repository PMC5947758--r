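#' Read FASTA sequences into a tibble
#'
#' Sequences are uppercased on read. Optional entry metadata may be carried
#' on the header line as `key=value` tokens after the identifier, e.g.
#' `>1abc_A resolution=1.50 r_value=0.180`; unrecognised tokens are ignored.
#'
#' @param text character vector of lines, a single string, or a file path
#' @return tibble with columns `id`, `sequence`, `resolution`, `r_value`
#' @export
read_fasta <- function(text) {
  lines <- as_text_lines(text)
  lines <- lines[str_trim(lines) != ""]
  hdr <- grep("^>", lines)
  if (length(hdr) == 0) abort("no FASTA headers found")
  ends <- c(hdr[-1] - 1L, length(lines))
  recs <- purrr::map2(hdr, ends, function(h, e) {
    toks <- strsplit(str_trim(sub("^>", "", lines[h])), "\\s+")[[1]]
    body <- if (e > h) paste(lines[(h + 1):e], collapse = "") else ""
    body <- toupper(gsub("\\s", "", body))
    if (nchar(body) == 0) abort(sprintf("empty sequence body for '%s'", toks[1]))
    meta <- header_meta(toks[-1])
    tibble(id = toks[1], sequence = body,
           resolution = meta$resolution, r_value = meta$r_value)
  })
  dplyr::bind_rows(recs)
}

header_meta <- function(tokens) {
  out <- list(resolution = NA_real_, r_value = NA_real_)
  kv <- grep("=", tokens, value = TRUE)
  for (t in kv) {
    p <- strsplit(t, "=", fixed = TRUE)[[1]]
    if (p[1] %in% names(out)) out[[p[1]]] <- as.numeric(p[2])
  }
  out
}

as_text_lines <- function(text) {
  if (length(text) == 1 && !grepl("\n", text) && file.exists(text)) {
    text <- readLines(text, warn = FALSE)
  }
  unlist(strsplit(text, "\n", fixed = TRUE), use.names = FALSE)
}

#' Write sequences as FASTA
#'
#' Sequence lines are wrapped at 60 columns; metadata columns present in the
#' input tibble are emitted as `key=value` header tokens, so
#' `read_fasta(write_fasta(x))` is an exact round trip.
#'
#' @param records tibble with columns `id`, `sequence` and optionally
#'   `resolution`, `r_value`
#' @param path optional file path
#' @return FASTA text as one string
#' @export
write_fasta <- function(records, path = NULL) {
  recs <- as_tibble(records)
  res_col <- if ("resolution" %in% names(recs)) recs$resolution else rep(NA, nrow(recs))
  rv_col <- if ("r_value" %in% names(recs)) recs$r_value else rep(NA, nrow(recs))
  out <- unlist(purrr::pmap(list(recs$id, recs$sequence, res_col, rv_col),
    function(id, seqs, res, rv) {
      hdr <- paste0(">", id)
      if (!is.na(res)) hdr <- sprintf("%s resolution=%.2f", hdr, res)
      if (!is.na(rv)) hdr <- sprintf("%s r_value=%.3f", hdr, rv)
      c(hdr, wrap60(seqs))
    }))
  txt <- paste(c(out, ""), collapse = "\n")
  if (!is.null(path)) {
    writeLines(out, path)
    return(invisible(txt))
  }
  txt
}

wrap60 <- function(s) {
  n <- nchar(s)
  starts <- seq(1, n, by = 60)
  substring(s, starts, pmin(starts + 59, n))
}

#' Write a pairwise target/hit alignment in PIR format
#'
#' Emits the two gapped rows in the PIR dialect used by alignment-driven
#' model-editing programs: `>P1;<id>` header, a free-text description line,
#' and the gapped sequence terminated by `*`. Gaps are written as `-`.
#'
#' @param ids length-2 character vector: target id, hit id
#' @param rows length-2 character vector of equal-length gapped rows
#' @param descriptions optional length-2 description lines
#' @param path optional file path
#' @return PIR text as one string
#' @export
write_pir_pairwise <- function(ids, rows, descriptions = c("sequence", "structure"),
                               path = NULL) {
  if (length(ids) != 2 || length(rows) != 2) abort("expected exactly two rows")
  if (nchar(rows[1]) != nchar(rows[2])) {
    abort("alignment rows differ in length")
  }
  out <- unlist(purrr::pmap(list(ids, rows, descriptions), function(id, row, d) {
    c(paste0(">P1;", id), d, wrap60(paste0(gsub("\\.", "-", row), "*")))
  }))
  txt <- paste(c(out, ""), collapse = "\n")
  if (!is.null(path)) {
    writeLines(out, path)
    return(invisible(txt))
  }
  txt
}

#' Read a PIR alignment file
#'
#' @param text lines, string or file path
#' @return tibble with columns `id`, `description`, `row` (gapped, `*` removed)
#' @export
read_pir <- function(text) {
  lines <- as_text_lines(text)
  hdr <- grep("^>P1;", lines)
  if (length(hdr) == 0) abort("no PIR entries found")
  ends <- c(hdr[-1] - 1L, length(lines))
  dplyr::bind_rows(purrr::map2(hdr, ends, function(h, e) {
    body <- paste(lines[(h + 2):e], collapse = "")
    body <- gsub("\\s", "", body)
    if (!grepl("\\*", body)) abort("PIR entry not terminated by '*'")
    tibble(id = sub("^>P1;", "", str_trim(lines[h])),
           description = str_trim(lines[h + 1]),
           row = toupper(sub("\\*.*$", "", body)))
  }))
}

#' Read a Stockholm 1.0 multiple sequence alignment
#'
#' Wrapped blocks are concatenated per identifier; `#=GF`/`#=GC`/`#=GS`/
#' `#=GR` annotation lines are ignored; `.` and `-` are both read as gaps
#' and normalised to `-`; residues are uppercased.
#'
#' @param text lines, string or file path
#' @return a tibble with columns `id` and `aligned` (equal-length gapped
#'   rows), carrying the alignment width in attribute `n_columns`
#' @export
read_stockholm <- function(text) {
  lines <- as_text_lines(text)
  if (length(lines) == 0 || !grepl("^# STOCKHOLM", lines[1])) {
    abort("not a Stockholm file (missing '# STOCKHOLM' header)")
  }
  if (!any(grepl("^//", lines))) abort("missing Stockholm terminator '//'")
  lines <- lines[seq_len(which(grepl("^//", lines))[1] - 1L)]
  seq_lines <- lines[!grepl("^#", lines) & str_trim(lines) != ""]
  rows <- list()
  order_ids <- character(0)
  for (ln in seq_lines) {
    parts <- strsplit(str_trim(ln), "\\s+")[[1]]
    if (length(parts) != 2) abort(sprintf("malformed Stockholm sequence line: '%s'", ln))
    id <- parts[1]
    if (is.null(rows[[id]])) {
      rows[[id]] <- parts[2]
      order_ids <- c(order_ids, id)
    } else {
      rows[[id]] <- paste0(rows[[id]], parts[2])
    }
  }
  aligned <- toupper(gsub("\\.", "-", unlist(rows[order_ids])))
  widths <- unique(nchar(aligned))
  if (length(widths) > 1) abort("Stockholm rows differ in length after concatenation")
  out <- tibble(id = order_ids, aligned = unname(aligned))
  attr(out, "n_columns") <- if (length(widths)) widths else 0L
  out
}

#' Read a whitespace-delimited hit-score table
#'
#' The table emulates the tabular output of a profile-HMM sequence search:
#' one row per hit with the model identifier and its full-sequence score
#' (bit-score-like). Lines beginning `#` are skipped; file order is kept.
#'
#' @param text lines, string or file path
#' @return tibble with columns `id` (character) and `score` (numeric)
#' @export
read_hit_table <- function(text) {
  lines <- as_text_lines(text)
  lines <- lines[str_trim(lines) != "" & !grepl("^\\s*#", lines)]
  if (length(lines) == 0) return(tibble(id = character(), score = double()))
  recs <- purrr::map(lines, function(ln) {
    parts <- strsplit(str_trim(ln), "\\s+")[[1]]
    if (length(parts) < 2) abort(sprintf("malformed hit line: '%s'", ln))
    sc <- suppressWarnings(as.numeric(parts[2]))
    if (is.na(sc)) abort(sprintf("non-numeric score in hit line: '%s'", ln))
    tibble(id = parts[1], score = sc)
  })
  dplyr::bind_rows(recs)
}
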