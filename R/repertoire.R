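#' Construct a TCR repertoire
#'
#' A repertoire is one individual's collection of unique CDR3 amino-acid
#' sequences together with their clonal abundances.
#'
#' @param individual_id Single string identifying the individual.
#' @param sequences Character vector of CDR3 amino-acid sequences; must be
#'   unique within the repertoire.
#' @param abundances Numeric vector of positive clone abundances, one per
#'   sequence. Read counts are the usual input; real-valued weights are
#'   accepted because every downstream formula only uses abundance ratios.
#' @return An object of class `tcr_repertoire`: a list with elements
#'   `individual_id`, `sequences` and `abundances`.
#' @export
repertoire <- function(individual_id, sequences, abundances) {
  individual_id <- as.character(individual_id)
  sequences <- as.character(sequences)
  abundances <- as.numeric(abundances)
  if (length(individual_id) != 1L || is.na(individual_id) || !nzchar(individual_id))
    stop("individual_id must be a single non-empty string")
  if (length(sequences) != length(abundances))
    stop("sequences and abundances must have equal length")
  if (anyDuplicated(sequences))
    stop("sequences within one repertoire must be unique")
  if (length(sequences) && (any(!nzchar(sequences)) || anyNA(sequences)))
    stop("sequences must be non-empty strings")
  if (length(abundances) && (anyNA(abundances) || any(abundances <= 0)))
    stop("abundances must be positive")
  structure(list(individual_id = individual_id,
                 sequences = sequences,
                 abundances = abundances),
            class = "tcr_repertoire")
}

#' @export
print.tcr_repertoire <- function(x, ...) {
  cat(sprintf("<tcr_repertoire> %s: %d clones, total abundance %g\n",
              x$individual_id, length(x$sequences), sum(x$abundances)))
  invisible(x)
}

n_clones <- function(rep) length(rep$sequences)

valid_sequence <- function(seqs) {
  !grepl(paste0("[^", paste(AA_ALPHABET, collapse = ""), "]"), seqs)
}

#' Read TCR repertoires from a file
#'
#' Reads one file holding the repertoires of one or more individuals and
#' returns one [repertoire()] per distinct individual, with abundances
#' summed over duplicate (individual, sequence) rows.
#'
#' Two dialects are supported. The `"csv"` dialect is a comma-separated
#' file with columns `individual_id,sequence,abundance`. The `"airr"`
#' dialect is a tab-separated AIRR rearrangement table; the columns used
#' default to the AIRR-C schema names and can be overridden.
#'
#' @param path Path to the input file.
#' @param format `"csv"` or `"airr"`.
#' @param id_col,seq_col,count_col Column names for the AIRR dialect
#'   (defaults `repertoire_id`, `junction_aa`, `duplicate_count`).
#' @return List of `tcr_repertoire`, ordered lexicographically by id.
#' @export
read_repertoires <- function(path, format = c("csv", "airr"),
                             id_col = "repertoire_id",
                             seq_col = "junction_aa",
                             count_col = "duplicate_count") {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "csv") {
    df <- utils::read.csv(path, stringsAsFactors = FALSE,
                          colClasses = "character")
    need <- c("individual_id", "sequence", "abundance")
  } else {
    df <- utils::read.delim(path, stringsAsFactors = FALSE,
                            colClasses = "character")
    need <- c(id_col, seq_col, count_col)
  }
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols))
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "))
  df <- df[, need]
  names(df) <- c("individual_id", "sequence", "abundance")
  if (nrow(df) == 0L) return(list())
  ab <- suppressWarnings(as.numeric(df$abundance))
  bad <- which(is.na(ab) | ab != round(ab) | ab <= 0)
  if (length(bad))
    stop(sprintf("non-integer or non-positive abundance at data row %d: '%s'",
                 bad[1], df$abundance[bad[1]]))
  df$abundance <- ab
  agg <- stats::aggregate(abundance ~ individual_id + sequence, data = df,
                          FUN = sum)
  ids <- sort(unique(agg$individual_id))
  lapply(ids, function(id) {
    sub <- agg[agg$individual_id == id, , drop = FALSE]
    sub <- sub[order(sub$sequence), , drop = FALSE]
    repertoire(id, sub$sequence, sub$abundance)
  })
}

#' Write repertoires to a CSV file
#'
#' Inverse of the `"csv"` dialect of [read_repertoires()].
#'
#' @param reps List of `tcr_repertoire`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_repertoires <- function(reps, path) {
  df <- do.call(rbind, lapply(reps, function(r)
    data.frame(individual_id = r$individual_id, sequence = r$sequences,
               abundance = r$abundances, stringsAsFactors = FALSE)))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Filter repertoires by abundance, alphabet, and richness
#'
#' Applies the standard repertoire quality filter: clones with abundance
#' below `min_abundance` are removed, clones whose sequence contains any
#' character outside the 20 standard amino-acid letters are removed, and
#' individuals left with fewer than `min_unique_sequences` clones are
#' dropped entirely. Filtering never raises an error; everything removed
#' is tallied in the attached report.
#'
#' @param reps List of `tcr_repertoire`.
#' @param min_abundance Minimum clone abundance kept (default 2, i.e.
#'   singleton clones are removed).
#' @param min_unique_sequences Minimum number of surviving unique
#'   sequences for an individual to be kept (default 2).
#' @return Filtered list with attribute `"filter_report"`, a data frame
#'   with the number of clones removed per rule and individuals dropped.
#' @export
filter_repertoires <- function(reps, min_abundance = 2,
                               min_unique_sequences = 2) {
  n_low <- 0L; n_bad <- 0L; dropped <- character(0)
  out <- list()
  for (r in reps) {
    keep_ab <- r$abundances >= min_abundance
    n_low <- n_low + sum(!keep_ab)
    seqs <- r$sequences[keep_ab]; ab <- r$abundances[keep_ab]
    keep_ok <- valid_sequence(seqs) & nzchar(seqs)
    n_bad <- n_bad + sum(!keep_ok)
    seqs <- seqs[keep_ok]; ab <- ab[keep_ok]
    if (length(seqs) >= min_unique_sequences) {
      out[[length(out) + 1L]] <- repertoire(r$individual_id, seqs, ab)
    } else {
      dropped <- c(dropped, r$individual_id)
    }
  }
  report <- data.frame(
    rule = c("low_abundance_clones", "abnormal_letter_clones",
             "individuals_dropped"),
    removed = c(n_low, n_bad, length(dropped)),
    stringsAsFactors = FALSE)
  attr(report, "dropped_ids") <- dropped
  structure(out, filter_report = report)
}

#' Align repertoires with a covariate table
#'
#' Restricts a repertoire list and a covariate/phenotype table to their
#' common individuals, drops individuals with any missing covariate or
#' outcome value, and puts both in the canonical (lexicographic by id)
#' order that indexes every downstream matrix.
#'
#' @param reps List of `tcr_repertoire`.
#' @param covariates Data frame with one row per individual; the id column
#'   is named by `id_col`, all remaining columns are outcome/covariates.
#' @param id_col Name of the id column (default `"individual_id"`).
#' @return List with elements `repertoires` and `covariates`, both in the
#'   same canonical order.
#' @export
align_cohort <- function(reps, covariates, id_col = "individual_id") {
  if (!id_col %in% names(covariates))
    stop("covariate table lacks id column '", id_col, "'")
  complete <- stats::complete.cases(covariates)
  covariates <- covariates[complete, , drop = FALSE]
  rep_ids <- vapply(reps, function(r) r$individual_id, character(1))
  common <- sort(intersect(rep_ids, covariates[[id_col]]))
  if (length(common) == 0L)
    stop("no individuals shared between repertoires and covariate table")
  reps <- reps[match(common, rep_ids)]
  covariates <- covariates[match(common, covariates[[id_col]]), , drop = FALSE]
  rownames(covariates) <- NULL
  list(repertoires = reps, covariates = covariates)
}
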