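#' Construct a protein quantification matrix
#'
#' Bundles a protein-by-run abundance grid with its run design. Missing
#' values (`NA`) are a distinct state from zero intensity: `NA` means the
#' protein was not observed in that run, `0` means it was observed at zero
#' intensity. This distinction drives the unique-protein logic of the
#' differential-abundance caller.
#'
#' @param abundance numeric matrix, proteins in rows (rownames = protein
#'   IDs), runs in columns (colnames = run IDs). Present values must be
#'   >= 0; missing values are `NA`.
#' @param runs data.frame with columns `run_id`, `condition`, `bio_rep`,
#'   `tech_rep`, one row per column of `abundance` (matched by `run_id`).
#' @return an object of class `quant_matrix`: a list with elements
#'   `abundance` and `runs`.
#' @examples
#' ab <- matrix(2^rnorm(12, 20), 3, 4,
#'              dimnames = list(paste0("P", 1:3), paste0("r", 1:4)))
#' runs <- data.frame(run_id = paste0("r", 1:4),
#'                    condition = rep(c("IAA", "IAACon"), each = 2),
#'                    bio_rep = c(1, 2, 1, 2), tech_rep = 1)
#' q <- quant_matrix(ab, runs)
#' @export
quant_matrix <- function(abundance, runs) {
  if (!is.matrix(abundance) || !is.numeric(abundance))
    stop("'abundance' must be a numeric matrix")
  if (is.null(rownames(abundance)) || is.null(colnames(abundance)))
    stop("'abundance' must have protein IDs as rownames and run IDs as colnames")
  dup <- rownames(abundance)[duplicated(rownames(abundance))]
  if (length(dup))
    stop("duplicate protein ID(s): ", paste(unique(dup), collapse = ", "))
  if (any(abundance < 0, na.rm = TRUE))
    stop("negative intensity found; present intensities must be >= 0")
  req <- c("run_id", "condition", "bio_rep", "tech_rep")
  miss <- setdiff(req, names(runs))
  if (length(miss))
    stop("run design lacks column(s): ", paste(miss, collapse = ", "))
  runs <- as.data.frame(runs)[, req]
  if (anyDuplicated(runs$run_id))
    stop("duplicate run_id in design")
  if (!setequal(runs$run_id, colnames(abundance)))
    stop("run_id set in design does not match abundance columns; missing: ",
         paste(setdiff(runs$run_id, colnames(abundance)), collapse = ", "))
  runs <- runs[match(colnames(abundance), runs$run_id), , drop = FALSE]
  rownames(runs) <- NULL
  if (any(runs$bio_rep < 1) || any(runs$tech_rep < 1))
    stop("bio_rep and tech_rep must be positive integers")
  storage.mode(abundance) <- "double"
  structure(list(abundance = abundance, runs = runs), class = "quant_matrix")
}

#' @export
print.quant_matrix <- function(x, ...) {
  tab <- table(x$runs$condition)
  cat("quant_matrix: ", nrow(x$abundance), " proteins x ",
      ncol(x$abundance), " runs (",
      paste(names(tab), tab, sep = ": ", collapse = ", "), ")\n", sep = "")
  cat(sprintf("missing values: %d (%.1f%%)\n",
              sum(is.na(x$abundance)),
              100 * mean(is.na(x$abundance))))
  invisible(x)
}

#' @export
dim.quant_matrix <- function(x) dim(x$abundance)

#' Condition labels of a quant_matrix
#'
#' Unique condition labels in order of first appearance in the run design.
#' The first label is taken as the case (treatment) condition by default
#' throughout the package.
#'
#' @param quant a [quant_matrix()].
#' @return character vector of condition labels.
#' @export
conditions <- function(quant) {
  unique(quant$runs$condition)
}

#' Read a protein quantification table with its run design
#'
#' The quantification table is a delimited file whose first column
#' (`protein_id`) holds protein identifiers and whose remaining columns are
#' named by run ID. Empty cells and a configurable sentinel parse as
#' missing (`NA`), never as zero. The run design maps run IDs to
#' condition / biological replicate / technical replicate labels and may be
#' a YAML file (a mapping run_id -> {condition, bio_rep, tech_rep}) or a
#' TSV with columns `run_id`, `condition`, `bio_rep`, `tech_rep`.
#'
#' @param path path to the quantification table (TSV).
#' @param design path to the design file (YAML or TSV), or a data.frame.
#' @param na_strings cell values parsed as missing (besides empty cells).
#' @param sep field separator.
#' @return a [quant_matrix()].
#' @export
read_quant_table <- function(path, design, na_strings = c("NA", ""),
                             sep = "\t") {
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          na.strings = na_strings, check.names = FALSE,
                          colClasses = NA, stringsAsFactors = FALSE,
                          quote = "", comment.char = "")
  if (ncol(df) < 2)
    stop("quantification table needs a protein_id column plus run columns")
  ids <- as.character(df[[1]])
  dup <- unique(ids[duplicated(ids)])
  if (length(dup))
    stop("duplicate protein ID(s) in ", path, ": ",
         paste(dup, collapse = ", "))
  runs <- if (is.data.frame(design)) design else read_design(design)
  absent <- setdiff(runs$run_id, names(df)[-1])
  if (length(absent))
    stop("run column(s) in design absent from quantification table: ",
         paste(absent, collapse = ", "))
  ab <- as.matrix(df[, runs$run_id, drop = FALSE])
  if (!is.numeric(ab))
    stop("non-numeric abundance values in ", path)
  rownames(ab) <- ids
  quant_matrix(ab, runs)
}

#' Read a run design file
#'
#' @param path YAML (mapping run_id -> condition/bio_rep/tech_rep) or TSV
#'   with columns `run_id`, `condition`, `bio_rep`, `tech_rep`; format is
#'   chosen by file extension (`.yaml`/`.yml` vs anything else).
#' @return data.frame with columns `run_id`, `condition`, `bio_rep`,
#'   `tech_rep`.
#' @export
read_design <- function(path) {
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    y <- yaml::read_yaml(path)
    runs <- data.frame(
      run_id = names(y),
      condition = vapply(y, function(e) as.character(e$condition), ""),
      bio_rep = vapply(y, function(e) as.integer(e$bio_rep), 1L),
      tech_rep = vapply(y, function(e) as.integer(e$tech_rep), 1L),
      stringsAsFactors = FALSE)
    rownames(runs) <- NULL
    runs
  } else {
    utils::read.table(path, header = TRUE, sep = "\t",
                      stringsAsFactors = FALSE)
  }
}

#' Write a quantification matrix / run design to disk
#'
#' Inverse of [read_quant_table()] / [read_design()]: `NA` abundances are
#' written as empty cells, so missing and zero stay distinct on round trip.
#'
#' @param quant a [quant_matrix()].
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_quant_table <- function(quant, path) {
  df <- data.frame(protein_id = rownames(quant$abundance),
                   quant$abundance, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write_results(df, path)
}

#' @rdname write_quant_table
#' @param design data.frame run design (as in [quant_matrix()]).
#' @export
write_design <- function(design, path) {
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    y <- lapply(seq_len(nrow(design)), function(i)
      list(condition = design$condition[i],
           bio_rep = as.integer(design$bio_rep[i]),
           tech_rep = as.integer(design$tech_rep[i])))
    names(y) <- design$run_id
    yaml::write_yaml(y, path)
  } else {
    write_results(design, path)
  }
  invisible(path)
}

#' Write a result table as TSV
#'
#' Generic writer for the pipeline's record tables (DAP calls, cluster
#' candidates, expression ratios, ...). Floating-point values are written
#' with enough significant digits (15) to round-trip within 1e-6 relative;
#' `NA` is written as an empty cell.
#'
#' @param records a data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_results <- function(records, path) {
  records <- as.data.frame(records)
  out <- records
  for (j in seq_along(out))
    if (is.double(out[[j]]))
      out[[j]] <- ifelse(is.na(out[[j]]), NA,
                         formatC(out[[j]], digits = 15, format = "g"))
  ok <- tryCatch({
    utils::write.table(out, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, na = "")
    TRUE
  }, error = function(e) e, warning = function(w) w)
  if (!isTRUE(ok))
    stop("cannot write results to ", path, ": ", conditionMessage(ok))
  invisible(path)
}
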