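# Compound parsing, canonicalization and structure-based deduplication.
# Structure perception is delegated to OpenBabel via ChemmineR/ChemmineOB;
# the canonical isomeric SMILES string serves as the duplicate key.

#' Parse a compound table from SMILES, CSV or SDF
#'
#' Reads compound records without performing structure perception: one
#' record per input row (CSV), non-blank line (SMILES) or molecule block
#' (SDF), in file order.
#'
#' Input conventions:
#' \itemize{
#'   \item \code{smiles}: one SMILES per line, optionally followed by a
#'     whitespace-separated name; blank lines skipped.
#'   \item \code{csv}: comma-separated with a mandatory header containing
#'     at least \code{identifier}, \code{name}, \code{smiles}.
#'   \item \code{sdf}: V2000 SD file; molecule titles become identifiers,
#'     untitled blocks get the synthetic identifier \code{mol_<index>};
#'     SMILES are derived from the connection table.
#' }
#'
#' @param path path to the input file.
#' @param format one of \code{"smiles"}, \code{"csv"}, \code{"sdf"} or
#'   \code{"auto"} (guess from the file extension).
#' @param source tag recorded in the \code{source} column.
#' @return data.frame with columns \code{identifier}, \code{name},
#'   \code{smiles}, \code{source}, in input order.
#' @examples
#' f <- tempfile(fileext = ".csv")
#' writeLines(c("identifier,name,smiles", "cpd1,ethanol,CCO"), f)
#' parseCompoundTable(f)
#' @export
parseCompoundTable <- function(path, format = c("auto", "smiles", "csv", "sdf"),
                               source = "file") {
  format <- match.arg(format)
  if (!file.exists(path)) stop("input file not found: ", path)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext,
      smi = "smiles", smiles = "smiles", txt = "smiles",
      csv = "csv",
      sdf = "sdf", sd = "sdf",
      stop("cannot guess format from extension '", ext,
           "'; pass format= explicitly"))
  }
  out <- switch(format,
    smiles = .parseSmilesFile(path),
    csv = .parseCsvFile(path),
    sdf = .parseSdfFile(path))
  if (nrow(out) == 0L) stop("empty compound library: ", path)
  out$source <- source
  rownames(out) <- NULL
  out
}

.parseSmilesFile <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  if (!length(lines))
    return(data.frame(identifier = character(), name = character(),
                      smiles = character()))
  parts <- regmatches(lines, regexpr("\\s+", lines), invert = TRUE)
  smiles <- vapply(parts, `[`, "", 1L)
  name <- vapply(parts, function(p) if (length(p) > 1L) p[2L] else "", "")
  id <- ifelse(nzchar(name), name, paste0("mol_", seq_along(lines)))
  data.frame(identifier = id, name = name, smiles = smiles)
}

.parseCsvFile <- function(path) {
  head1 <- readLines(path, n = 1L, warn = FALSE)
  if (!length(head1)) stop("empty compound library: ", path)
  cols <- trimws(tolower(strsplit(head1, ",")[[1]]))
  need <- c("identifier", "name", "smiles")
  if (!all(need %in% cols))
    stop("malformed CSV header: need columns identifier, name, smiles; got: ",
         head1)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character")
  names(df) <- tolower(names(df))
  df[, need]
}

# Split raw V2000 molecule blocks on $$$$ and convert each through
# OpenBabel (robust to zero-bond molecules, which trip some SDF paths).
.parseSdfFile <- function(path) {
  lines <- readLines(path, warn = FALSE)
  ends <- grep("^\\$\\$\\$\\$", lines)
  if (!length(ends))
    return(data.frame(identifier = character(), name = character(),
                      smiles = character()))
  starts <- c(1L, head(ends, -1L) + 1L)
  blocks <- Map(function(s, e) lines[s:e], starts, ends)
  blocks <- Filter(function(b) any(grepl("V2000", b)), blocks)
  n <- length(blocks)
  titles <- vapply(blocks, function(b) trimws(b[1]), "")
  id <- ifelse(!nzchar(titles), paste0("mol_", seq_len(n)), titles)
  smiles <- vapply(blocks, function(b) {
    out <- tryCatch(
      ChemmineOB::convertFormat("SDF", "CAN",
                                paste0(paste(b, collapse = "\n"), "\n")),
      error = function(e) "")
    trimws(sub("\t.*$", "", out))
  }, "")
  data.frame(identifier = id, name = id, smiles = smiles)
}

#' Canonical isomeric structure key
#'
#' Maps a SMILES string to a canonical isomeric SMILES via OpenBabel, so
#' that two encodings of the same molecule (atom order, aromatic vs
#' Kekule form) map to the same key while stereoisomers keep distinct
#' keys. Unparseable or empty input yields \code{NA} rather than an
#' error; the validity filter consumes that state.
#'
#' @param smiles character vector of SMILES strings.
#' @return character vector of canonical keys, \code{NA} where the input
#'   could not be parsed.
#' @examples
#' canonicalStructureKey(c("OCC", "CCO"))  # identical keys
#' @export
canonicalStructureKey <- function(smiles) {
  vapply(as.character(smiles), function(s) {
    s <- trimws(s)
    if (is.na(s) || !nzchar(s)) return(NA_character_)
    out <- tryCatch(
      ChemmineOB::convertFormat("SMI", "CAN", paste0(s, "\n")),
      error = function(e) "")
    out <- trimws(sub("\t.*$", "", out))
    if (!nzchar(out)) NA_character_ else out
  }, "", USE.NAMES = FALSE)
}

#' Filter a compound table to valid, structurally unique records
#'
#' Applies the validity/deduplication filter: records with missing
#' SMILES are rejected first, then records whose SMILES cannot be
#' parsed, then structural duplicates (same canonical isomeric key as an
#' earlier record; first occurrence wins). Each rejected record carries
#' exactly one reason code, and kept + rejected partition the input.
#'
#' @param records data.frame as returned by [parseCompoundTable()]
#'   (columns \code{identifier}, \code{name}, \code{smiles}; a
#'   \code{source} column is carried through if present).
#' @return a [CompoundLibrary-class] whose \code{records} slot holds the
#'   kept rows (plus a \code{structure_key} column) in first-occurrence
#'   input order and whose \code{rejections} slot logs every removal.
#' @examples
#' tab <- data.frame(identifier = c("a", "b", "c"), name = "",
#'                   smiles = c("CCO", "OCC", ""))
#' lib <- filterValidUnique(tab)
#' records(lib)      # only "a" survives deduplication; "c" lacks SMILES
#' rejections(lib)
#' @export
filterValidUnique <- function(records) {
  stopifnot(is.data.frame(records),
            all(c("identifier", "smiles") %in% names(records)))
  n <- nrow(records)
  if (!"name" %in% names(records)) records$name <- records$identifier
  if (!"source" %in% names(records)) records$source <- "unknown"
  smiles <- trimws(as.character(records$smiles))
  missing <- is.na(smiles) | !nzchar(smiles)
  key <- rep(NA_character_, n)
  key[!missing] <- canonicalStructureKey(smiles[!missing])
  unparseable <- !missing & is.na(key)
  dup <- !missing & !unparseable & duplicated(key)
  keep <- !missing & !unparseable & !dup
  reason <- character(n)
  reason[missing] <- "missing-smiles"
  reason[unparseable] <- "unparseable-smiles"
  reason[dup] <- "duplicate-structure"
  kept <- records[keep, c("identifier", "name", "smiles", "source"),
                  drop = FALSE]
  kept$structure_key <- key[keep]
  if (anyDuplicated(kept$identifier)) {
    ii <- which(duplicated(kept$identifier))
    kept$identifier[ii] <- paste0(kept$identifier[ii], "_", ii + 1L)
  }
  rej <- data.frame(identifier = records$identifier[!keep],
                    reason = reason[!keep])
  rownames(kept) <- rownames(rej) <- NULL
  if (!nrow(kept)) warning("no valid unique compounds retained")
  new("CompoundLibrary", records = kept, rejections = rej)
}

#' Write a compound library (kept records and rejection log) as CSV
#'
#' @param lib a [CompoundLibrary-class].
#' @param keptPath output CSV for kept records.
#' @param logPath optional output CSV for the rejection log.
#' @return invisibly, \code{keptPath}.
#' @export
writeLibrary <- function(lib, keptPath, logPath = NULL) {
  stopifnot(is(lib, "CompoundLibrary"))
  utils::write.csv(records(lib), keptPath, row.names = FALSE)
  if (!is.null(logPath))
    utils::write.csv(rejections(lib), logPath, row.names = FALSE)
  invisible(keptPath)
}
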