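#' @importFrom utils read.delim write.table
NULL

normSymbol <- function(x) toupper(trimws(as.character(x)))

truthy <- function(x) tolower(trimws(as.character(x))) %in% c("t", "true", "1", "yes")

#' Read a STRING-style interaction edge list
#'
#' Parses a tab-separated interaction file in the STRING links dialect
#' (header `protein1`, `protein2`, `combined_score`) and retains rows at or
#' above a combined-score confidence threshold. Gene symbols are
#' uppercased and whitespace-stripped; file row order is preserved.
#' Self-pairs are legal in raw exports and are kept here but flagged with a
#' warning — dropping them is [buildNetwork()]'s job.
#'
#' @param path path to the TSV file.
#' @param scoreThreshold integer in \[0, 1000\]; rows with
#'   `combined_score` below it are dropped. Default 400, the conventional
#'   STRING "medium confidence" cutoff.
#' @return data.frame of interaction records with columns `proteinA`,
#'   `proteinB` (character) and `combinedScore` (integer).
#' @examples
#' f <- tempfile(fileext = ".tsv")
#' writeInteractions(data.frame(proteinA = "TP53", proteinB = "AKT1",
#'                              combinedScore = 900L), f)
#' readInteractions(f, scoreThreshold = 0)
#' @export
readInteractions <- function(path, scoreThreshold = 400L) {
  if (!file.exists(path)) stop("interaction file not found: ", path)
  if (scoreThreshold < 0 || scoreThreshold > 1000)
    stop("scoreThreshold must lie in [0, 1000]")
  raw <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("protein1", "protein2", "combined_score")
  missing <- setdiff(need, names(raw))
  if (length(missing))
    stop("interaction file lacks required column(s): ",
         paste(missing, collapse = ", "))
  score <- suppressWarnings(as.integer(raw$combined_score))
  bad <- which(is.na(score) | score < 0 | score > 1000)
  if (length(bad))
    stop("combined_score outside [0, 1000] or unparseable at file line(s): ",
         paste(bad + 1L, collapse = ", "))  # +1 for the header line
  rec <- data.frame(proteinA = normSymbol(raw$protein1),
                    proteinB = normSymbol(raw$protein2),
                    combinedScore = score,
                    stringsAsFactors = FALSE)
  nSelf <- sum(rec$proteinA == rec$proteinB)
  if (nSelf)
    warning(nSelf, " self-pair record(s) present; they will be dropped at network build")
  rec[rec$combinedScore >= scoreThreshold, , drop = FALSE]
}

#' Write a STRING-style interaction edge list
#'
#' Inverse of [readInteractions()]: writes the `protein1` / `protein2` /
#' `combined_score` TSV dialect, re-readable with identical content at
#' threshold 0.
#'
#' @param records data.frame with columns `proteinA`, `proteinB`,
#'   `combinedScore`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeInteractions <- function(records, path) {
  stopifnot(all(c("proteinA", "proteinB", "combinedScore") %in% names(records)))
  if (nrow(records) && (any(records$combinedScore < 0) ||
                        any(records$combinedScore > 1000)))
    stop("combinedScore must lie in [0, 1000]")
  out <- data.frame(protein1 = records$proteinA,
                    protein2 = records$proteinB,
                    combined_score = as.integer(records$combinedScore))
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a STRING-style protein-actions file
#'
#' Parses the STRING protein-actions dialect (header `item_id_a`,
#' `item_id_b`, `mode`, `action`, `is_directional`, `a_is_acting`) into
#' typed action records. Only the three modes the screening pipeline
#' understands — `expression`, `activation`, `inhibition` — are kept; rows
#' with any other mode (e.g. `binding`, `catalysis`) are skipped with a
#' message stating the count. The acting item becomes the source when
#' `a_is_acting` is false the roles swap; rows with `is_directional` false
#' are returned with `directed = FALSE` and ignored later by role
#' classification.
#'
#' Signs follow the relation semantics: activation is always `positive`,
#' inhibition always `negative`, and expression takes its sign
#' (up/downregulation) from the `action` column (`positive` / `negative`),
#' falling back to `unspecified` when blank.
#'
#' @param path path to the TSV file.
#' @return data.frame of action records with columns `source`, `target`,
#'   `mode`, `sign` (character) and `directed` (logical).
#' @export
readActions <- function(path) {
  if (!file.exists(path)) stop("action file not found: ", path)
  raw <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE,
                    colClasses = "character")
  need <- c("item_id_a", "item_id_b", "mode", "action",
            "is_directional", "a_is_acting")
  missing <- setdiff(need, names(raw))
  if (length(missing))
    stop("action file lacks required column(s): ",
         paste(missing, collapse = ", "))
  if (!nrow(raw))
    return(data.frame(source = character(), target = character(),
                      mode = character(), sign = character(),
                      directed = logical(), stringsAsFactors = FALSE))
  malformed <- which(is.na(raw$item_id_a) | is.na(raw$item_id_b) |
                     is.na(raw$mode) |
                     !nzchar(trimws(raw$item_id_a)) |
                     !nzchar(trimws(raw$item_id_b)) |
                     !nzchar(trimws(raw$mode)))
  if (length(malformed))
    stop("malformed action row(s) at file line(s): ",
         paste(malformed + 1L, collapse = ", "))
  mode <- tolower(trimws(raw$mode))
  keep <- mode %in% ACTION_MODES
  if (any(!keep))
    message(sum(!keep), " action row(s) with unrecognized mode skipped")
  raw <- raw[keep, , drop = FALSE]
  mode <- mode[keep]
  if (!nrow(raw))
    return(data.frame(source = character(), target = character(),
                      mode = character(), sign = character(),
                      directed = logical(), stringsAsFactors = FALSE))
  a <- normSymbol(raw$item_id_a)
  b <- normSymbol(raw$item_id_b)
  acting <- truthy(raw$a_is_acting)
  src <- ifelse(acting, a, b)
  tgt <- ifelse(acting, b, a)
  act <- tolower(trimws(raw$action))
  sign <- ifelse(mode == "activation", "positive",
          ifelse(mode == "inhibition", "negative",
          ifelse(act %in% c("positive", "upregulation"), "positive",
          ifelse(act %in% c("negative", "downregulation"), "negative",
                 "unspecified"))))
  data.frame(source = src, target = tgt, mode = mode, sign = sign,
             directed = truthy(raw$is_directional),
             stringsAsFactors = FALSE)
}

#' Write a STRING-style protein-actions file
#'
#' Inverse of [readActions()] for directed records: the source is written
#' as `item_id_a` with `a_is_acting = t`, and the sign of expression
#' records goes into the `action` column.
#'
#' @param records data.frame with columns `source`, `target`, `mode`,
#'   `sign`, `directed`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeActions <- function(records, path) {
  stopifnot(all(c("source", "target", "mode", "sign", "directed") %in%
                names(records)))
  out <- data.frame(item_id_a = records$source,
                    item_id_b = records$target,
                    mode = records$mode,
                    action = ifelse(records$sign == "unspecified", "",
                                    records$sign),
                    is_directional = ifelse(records$directed, "t", "f"),
                    a_is_acting = "t")
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
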