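#' Acquisition metadata for one fMRI run
#'
#' @param tr seconds per volume (> 0).
#' @param n_volumes number of volumes in the run (>= 1).
#' @param voxel_size mm triple, all components > 0.
#' @param fwhm_smooth spatial smoothing kernel FWHM in mm (>= 0).
#' @return list of class `acquisition_params`.
#' @export
acquisition_params <- function(tr = 1, n_volumes, voxel_size = c(3, 3, 3),
                               fwhm_smooth = 8) {
  stopifnot(is.numeric(tr), tr > 0,
            is.numeric(n_volumes), n_volumes >= 1,
            length(voxel_size) == 3, all(voxel_size > 0),
            fwhm_smooth >= 0)
  structure(list(tr = tr, n_volumes = as.integer(n_volumes),
                 voxel_size = as.numeric(voxel_size),
                 fwhm_smooth = fwhm_smooth),
            class = "acquisition_params")
}

#' Blocked experimental design for one run
#'
#' Validates a table of condition blocks against the acquisition metadata.
#' Blocks must be non-overlapping; gaps between blocks are permitted and are
#' treated as unassigned volumes that belong to neither task nor rest.
#'
#' @param study_id study label, e.g. "sentence", "word" or "tom".
#' @param blocks data.frame with columns `onset` (s, >= 0), `duration`
#'   (s, > 0) and `condition` (character; the label "rest" marks fixation).
#' @param acquisition an [acquisition_params()].
#' @return list of class `session_design` with blocks sorted by onset.
#' @export
session_design <- function(study_id, blocks, acquisition) {
  stopifnot(inherits(acquisition, "acquisition_params"),
            is.data.frame(blocks),
            all(c("onset", "duration", "condition") %in% names(blocks)))
  blocks <- blocks[order(blocks$onset), c("onset", "duration", "condition"),
                   drop = FALSE]
  rownames(blocks) <- NULL
  blocks$onset <- as.numeric(blocks$onset)
  blocks$duration <- as.numeric(blocks$duration)
  blocks$condition <- as.character(blocks$condition)
  if (nrow(blocks) == 0) stop("design has no blocks")
  if (any(!is.finite(blocks$onset)) || any(!is.finite(blocks$duration)))
    stop("non-finite onset or duration")
  if (any(blocks$onset < 0)) stop("block onsets must be >= 0")
  if (any(blocks$duration <= 0)) stop("block durations must be > 0")
  ends <- blocks$onset + blocks$duration
  if (nrow(blocks) > 1) {
    overlap <- blocks$onset[-1] < ends[-nrow(blocks)] - 1e-9
    if (any(overlap))
      stop("overlapping blocks at rows ",
           paste(which(overlap), which(overlap) + 1, sep = "/", collapse = ", "))
  }
  if (!any(blocks$condition == "rest"))
    stop("design must contain at least one rest block")
  total_time <- max(ends)
  if (total_time > acquisition$n_volumes * acquisition$tr + 1e-9)
    stop("blocks extend past the end of the run (",
         total_time, " s > ", acquisition$n_volumes * acquisition$tr, " s)")
  structure(list(study_id = study_id, blocks = blocks,
                 acquisition = acquisition),
            class = "session_design")
}

#' @export
print.session_design <- function(x, ...) {
  cat("session_design <", x$study_id, ">: ", nrow(x$blocks), " blocks, ",
      sum(x$blocks$condition == "rest"), " rest, ",
      x$acquisition$n_volumes, " volumes @ TR ", x$acquisition$tr, " s\n",
      sep = "")
  invisible(x)
}

#' Read a block design from a TSV or JSON file
#'
#' TSV files carry the columns `onset`, `duration`, `condition` (tab
#' separated, header required).  JSON files carry an object with a `blocks`
#' array of such records and optionally `study_id` and `acquisition`
#' (`tr`, `n_volumes`, `voxel_size`, `fwhm`).  Acquisition metadata may also
#' be supplied via a sidecar JSON (same path with extension `.json` replaced
#' or given explicitly) or as the `acquisition` argument, which wins.
#'
#' @param path design file path.
#' @param acquisition optional [acquisition_params()] overriding any sidecar.
#' @param sidecar optional path to an acquisition JSON sidecar.
#' @param study_id study label used when the file does not carry one.
#' @return a validated [session_design()].
#' @export
load_design <- function(path, acquisition = NULL, sidecar = NULL,
                        study_id = "unnamed") {
  if (!file.exists(path)) stop("design file not found: ", path)
  is_json <- grepl("\\.json$", path, ignore.case = TRUE)
  if (is_json) {
    obj <- tryCatch(jsonlite::read_json(path, simplifyVector = TRUE),
                    error = function(e)
                      stop("parse error in ", path, ": ", conditionMessage(e)))
    blocks <- as.data.frame(obj$blocks)
    if (!is.null(obj$study_id)) study_id <- obj$study_id
    if (is.null(acquisition) && !is.null(obj$acquisition))
      acquisition <- acq_from_list(obj$acquisition)
  } else {
    if (file.size(path) == 0) stop("parse error in ", path, ": empty file")
    blocks <- tryCatch(
      utils::read.delim(path, header = TRUE, sep = "\t",
                        stringsAsFactors = FALSE),
      error = function(e)
        stop("parse error in ", path, ": ", conditionMessage(e)))
    if (!all(c("onset", "duration", "condition") %in% names(blocks)))
      stop("parse error in ", path,
           ": line 1 must be a header 'onset\tduration\tcondition'")
    bad <- which(is.na(suppressWarnings(as.numeric(blocks$onset))) |
                   is.na(suppressWarnings(as.numeric(blocks$duration))))
    if (length(bad))
      stop("parse error in ", path, ": non-numeric timing at data line ",
           bad[1])
  }
  if (is.null(acquisition)) {
    sc <- sidecar
    if (is.null(sc)) sc <- sub("\\.[^.]+$", ".json", path)
    if (!is_json && file.exists(sc))
      acquisition <- acq_from_list(jsonlite::read_json(sc,
                                                       simplifyVector = TRUE))
  }
  if (is.null(acquisition)) {
    # fall back to a TR-1s run just long enough for the blocks
    nv <- ceiling(max(blocks$onset + blocks$duration))
    acquisition <- acquisition_params(tr = 1, n_volumes = nv)
  }
  session_design(study_id, blocks, acquisition)
}

acq_from_list <- function(x) {
  acquisition_params(
    tr = x$tr %||% 1,
    n_volumes = x$n_volumes,
    voxel_size = x$voxel_size %||% c(3, 3, 3),
    fwhm_smooth = x$fwhm %||% x$fwhm_smooth %||% 8)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a block design (and acquisition sidecar) to TSV + JSON
#'
#' @param design a [session_design()].
#' @param path TSV output path; a sidecar `.json` with acquisition metadata
#'   is written next to it.
#' @return `path`, invisibly.
#' @export
write_design <- function(design, path) {
  stopifnot(inherits(design, "session_design"))
  utils::write.table(design$blocks, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  sc <- sub("\\.[^.]+$", ".json", path)
  a <- design$acquisition
  jsonlite::write_json(list(study_id = design$study_id, tr = a$tr,
                            n_volumes = a$n_volumes,
                            voxel_size = a$voxel_size,
                            fwhm = a$fwhm_smooth),
                       sc, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' The three built-in blocked study designs
#'
#' Returns the sentence-comprehension, word-judgment and intentional-
#' causality (theory-of-mind) designs used throughout the package demo:
#'
#' * `sentence`: 8 task blocks of 36 s (six 6-s sentence trials each,
#'   alternating pun/literal) interleaved with 5 fixation blocks of 24 s.
#' * `word`: 9 judgment blocks of 24 s (self / other / case-judgment,
#'   three each) interleaved with 7 fixation blocks of 15 s.
#' * `tom`: 4 cartoon-vignette blocks (11-s trials; 6+5+6+5 vignettes,
#'   alternating intentional/physical) interleaved with 5 fixation blocks
#'   of 24 s.
#'
#' Across the three runs there are 17 fixation (rest) blocks totalling
#' 345 s.  Published sources fix the block durations and counts; the
#' orderings are one deterministic choice among the counterbalanced orders.
#'
#' @param tr seconds per volume (default 1).
#' @return named list of three [session_design()] objects.
#' @export
canonical_designs <- function(tr = 1) {
  seq_design <- function(study_id, durations, conditions) {
    onset <- cumsum(c(0, durations[-length(durations)]))
    blocks <- data.frame(onset = onset, duration = durations,
                         condition = conditions)
    nv <- ceiling(sum(durations) / tr)
    session_design(study_id, blocks,
                   acquisition_params(tr = tr, n_volumes = nv))
  }

  # sentence: R T T R T T R T T R T T R  (5 rest x 24 s, 8 task x 36 s)
  sent_pat <- c("R", "T", "T", "R", "T", "T", "R", "T", "T", "R", "T", "T", "R")
  sent_dur <- ifelse(sent_pat == "R", 24, 36)
  task_lab <- rep(c("pun", "literal"), 4)
  sent_cond <- sent_pat
  sent_cond[sent_pat == "R"] <- "rest"
  sent_cond[sent_pat == "T"] <- task_lab
  sentence <- seq_design("sentence", sent_dur, sent_cond)

  # word: (R T) x 7 then T T  (7 rest x 15 s, 9 task x 24 s)
  word_pat <- c(rep(c("R", "T"), 7), "T", "T")
  word_dur <- ifelse(word_pat == "R", 15, 24)
  word_lab <- rep(c("self", "other", "case"), 3)
  word_cond <- word_pat
  word_cond[word_pat == "R"] <- "rest"
  word_cond[word_pat == "T"] <- word_lab
  word <- seq_design("word", word_dur, word_cond)

  # tom: R T R T R T R T R  (5 rest x 24 s; 22 vignettes x 11 s in 4 blocks)
  tom_pat <- c("R", "T", "R", "T", "R", "T", "R", "T", "R")
  tom_dur <- c(24, 66, 24, 55, 24, 66, 24, 55, 24)
  tom_cond <- c("rest", "intentional", "rest", "physical", "rest",
                "intentional", "rest", "physical", "rest")
  tom <- seq_design("tom", tom_dur, tom_cond)

  list(sentence = sentence, word = word, tom = tom)
}

# seconds of rest in a design
rest_seconds <- function(design) {
  b <- design$blocks
  sum(b$duration[b$condition == "rest"])
}

# number of rest blocks in a design
n_rest_blocks <- function(design) {
  sum(design$blocks$condition == "rest")
}
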