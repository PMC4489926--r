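# Trajectory and ledger persistence.  XYZ is used for coordinates (beads
# are not atoms, so PDB buys nothing); ledgers are plain CSV, appendable
# and greppable; summaries are JSON-friendly lists.

#' Write frames to an XYZ trajectory file
#'
#' One block per frame: bead count, free-form comment line (step count
#' and adhesion flags), then one \code{C x y z} row per bead with 9
#' significant digits.
#'
#' @param frames a single N x 3 matrix or a list of them.
#' @param path output file.
#' @param comments character vector of per-frame comment lines.
#' @export
write_xyz <- function(frames, path, comments = NULL) {
  if (is.matrix(frames)) frames <- list(frames)
  if (is.null(comments)) comments <- rep("", length(frames))
  stopifnot(length(comments) == length(frames))
  con <- file(path, "w")
  on.exit(close(con))
  for (k in seq_along(frames)) {
    fr <- frames[[k]]
    writeLines(c(as.character(nrow(fr)), comments[k]), con)
    writeLines(sprintf("C %.9g %.9g %.9g", fr[, 1], fr[, 2], fr[, 3]), con)
  }
  invisible(path)
}

#' Read an XYZ trajectory file
#'
#' @param path input file.
#' @return list with \code{frames} (list of N x 3 matrices) and
#'   \code{comments}; parse errors report the offending line number.
#' @export
read_xyz <- function(path) {
  lines <- readLines(path)
  frames <- list()
  comments <- character(0)
  i <- 1L
  while (i <= length(lines)) {
    if (!grepl("^\\s*\\d+\\s*$", lines[i]))
      stop(sprintf("XYZ parse error at line %d: expected atom count", i))
    n <- as.integer(lines[i])
    if (i + 1 + n > length(lines))
      stop(sprintf("XYZ parse error at line %d: truncated frame", i))
    comments <- c(comments, lines[i + 1])
    block <- lines[(i + 2):(i + 1 + n)]
    parts <- strsplit(trimws(block), "\\s+")
    bad <- which(lengths(parts) != 4)
    if (length(bad))
      stop(sprintf("XYZ parse error at line %d: malformed atom row",
                   i + 1 + bad[1]))
    m <- matrix(as.numeric(unlist(lapply(parts, `[`, 2:4))),
                ncol = 3, byrow = TRUE)
    if (anyNA(m))
      stop(sprintf("XYZ parse error at line %d: non-numeric coordinate",
                   i + 2))
    frames <- c(frames, list(m))
    i <- i + 2L + n
  }
  list(frames = frames, comments = comments)
}

ledger_columns <- c("run_id", "config_hash", "seed", "l_x", "l_y",
                    "circularized", "censored", "steps", "knot_label",
                    "det_minus1", "det_minus2", "loop_closed", "relevant",
                    "error")

#' Append rows to a run ledger (CSV)
#'
#' Append-only; the header is written once.  Concurrent campaigns should
#' write per-batch files and merge at report time.
#'
#' @param rows data frame of ledger rows.
#' @param path CSV path.
#' @export
ledger_append <- function(rows, path) {
  stopifnot(all(ledger_columns %in% names(rows)))
  new <- !file.exists(path)
  write.table(rows[, ledger_columns], path, sep = ",", append = !new,
              col.names = new, row.names = FALSE, qmethod = "double")
  invisible(path)
}

#' Load and validate a run ledger
#'
#' Checks the schema and the structural invariants: every run ends
#' either circularized or censored (never both), knot fields are present
#' iff the run circularized, and relevance is assessed only for knotted
#' runs with a closed loop.
#'
#' @param path CSV path.
#' @return the ledger data frame.
#' @export
ledger_load <- function(path) {
  hdr <- names(read.csv(path, nrows = 1, check.names = FALSE))
  missing <- setdiff(ledger_columns, hdr)
  if (length(missing))
    stop("ledger schema drift: missing columns ",
         paste(missing, collapse = ", "))
  want <- c(run_id = "character", config_hash = "character",
            knot_label = "character", error = "character")
  led <- read.csv(path, stringsAsFactors = FALSE,
                  colClasses = want[intersect(names(want), hdr)])
  if (any(led$circularized == led$censored))
    stop("ledger invariant violated: circularized XOR censored")
  if (any(led$circularized & is.na(led$knot_label)))
    stop("ledger invariant violated: circularized run without knot fields")
  if (any(!led$circularized & !is.na(led$knot_label)))
    stop("ledger invariant violated: censored run with knot fields")
  bad_rel <- !is.na(led$relevant) &
    !(led$knot_label %in% setdiff(unique(led$knot_label), "0_1") &
        led$loop_closed %in% TRUE)
  if (any(bad_rel, na.rm = TRUE))
    stop("ledger invariant violated: relevance without closed knotted loop")
  led
}
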