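#' Construct a compound-by-sample profile matrix
#'
#' A \code{profile_matrix} bundles a non-negative abundance matrix
#' (compounds in rows, samples in columns) with per-compound metadata and
#' per-sample group labels. An abundance of exactly zero means the compound
#' was not detected in that sample; missing cells are imputed to zero at
#' construction, mirroring the standard treatment of undetected peaks in
#' untargeted GC-MS peak tables.
#'
#' @param abundance numeric matrix, compounds x samples; \code{NA} cells are
#'   set to 0. Row and column names are overridden by \code{compounds} and
#'   \code{sample_ids} when supplied.
#' @param compounds data.frame of compound metadata with columns
#'   \code{compound_id}, \code{name}, \code{mass}, \code{metabolite},
#'   \code{is_contaminant}. Missing columns other than \code{compound_id}
#'   are filled with defaults.
#' @param sample_ids character vector of sample identifiers.
#' @param groups factor or character vector of per-sample labels with
#'   exactly two levels, \code{"case"} and \code{"control"}.
#' @return An object of class \code{profile_matrix}: a list with elements
#'   \code{abundance}, \code{compounds}, \code{sample_ids}, \code{groups}.
#' @examples
#' pm <- profile_matrix(matrix(c(1, 0, NA, 2, 5, 3), nrow = 3),
#'                      compounds = data.frame(compound_id = c("c1", "c2", "c3")),
#'                      sample_ids = c("s1", "s2"),
#'                      groups = c("case", "control"))
#' pm$abundance["c3", "s1"]  # imputed to 0
#' @export
profile_matrix <- function(abundance, compounds, sample_ids, groups) {
  abundance <- as.matrix(abundance)
  storage.mode(abundance) <- "double"
  compounds <- as.data.frame(compounds, stringsAsFactors = FALSE)
  if (is.null(compounds$compound_id))
    stop("compound metadata must contain a 'compound_id' column")
  compounds$compound_id <- as.character(compounds$compound_id)
  if (is.null(compounds$name)) compounds$name <- compounds$compound_id
  if (is.null(compounds$mass)) compounds$mass <- 100L
  if (is.null(compounds$metabolite)) compounds$metabolite <- "unknown"
  if (is.null(compounds$is_contaminant)) compounds$is_contaminant <- FALSE
  compounds$mass <- as.integer(compounds$mass)
  compounds$is_contaminant <- as.logical(compounds$is_contaminant)
  sample_ids <- as.character(sample_ids)
  groups <- as.character(groups)

  if (nrow(abundance) != nrow(compounds))
    stop("abundance has ", nrow(abundance), " rows but metadata describes ",
         nrow(compounds), " compounds")
  if (ncol(abundance) != length(sample_ids))
    stop("abundance has ", ncol(abundance), " columns but ",
         length(sample_ids), " sample ids were given")
  if (length(groups) != length(sample_ids))
    stop("'groups' must have one label per sample")

  dup <- compounds$compound_id[duplicated(compounds$compound_id)]
  if (length(dup))
    stop("duplicated compound_id: ", paste(unique(dup), collapse = ", "))
  if (anyDuplicated(sample_ids))
    stop("duplicated sample ids: ",
         paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "))
  if (any(is.na(compounds$mass)) || any(compounds$mass <= 0))
    stop("compound 'mass' must be a positive integer")

  bad_grp <- setdiff(unique(groups), c("case", "control"))
  if (length(bad_grp))
    stop("group labels must be 'case' or 'control'; found: ",
         paste(bad_grp, collapse = ", "))
  if (!all(c("case", "control") %in% groups))
    stop("need at least one case and one control sample")

  abundance[is.na(abundance)] <- 0
  if (any(abundance < 0)) {
    idx <- which(abundance < 0, arr.ind = TRUE)[1, ]
    stop("negative abundance at compound '", compounds$compound_id[idx[1]],
         "', sample '", sample_ids[idx[2]], "'")
  }
  dimnames(abundance) <- list(compounds$compound_id, sample_ids)

  structure(
    list(abundance = abundance, compounds = compounds,
         sample_ids = sample_ids,
         groups = factor(groups, levels = c("case", "control"))),
    class = "profile_matrix")
}

#' @export
print.profile_matrix <- function(x, ...) {
  tab <- table(x$groups)
  cat("profile_matrix: ", nrow(x$abundance), " compounds x ",
      ncol(x$abundance), " samples (", tab[["case"]], " case, ",
      tab[["control"]], " control)\n", sep = "")
  cat(sprintf("  zero (undetected) cells: %.1f%%\n",
              100 * mean(x$abundance == 0)))
  n_cont <- sum(x$compounds$is_contaminant)
  if (n_cont) cat("  flagged contaminant compounds:", n_cont, "\n")
  invisible(x)
}

#' @export
dim.profile_matrix <- function(x) dim(x$abundance)

#' Subset a profile matrix by sample ids
#'
#' @param pm a \code{profile_matrix}.
#' @param sample_ids character vector of sample ids to keep, in the given order.
#' @return A \code{profile_matrix} restricted to those samples.
#' @export
subset_samples <- function(pm, sample_ids) {
  stopifnot(inherits(pm, "profile_matrix"))
  missing <- setdiff(sample_ids, pm$sample_ids)
  if (length(missing))
    stop("unknown sample id(s): ", paste(missing, collapse = ", "))
  idx <- match(sample_ids, pm$sample_ids)
  profile_matrix(pm$abundance[, idx, drop = FALSE], pm$compounds,
                 pm$sample_ids[idx], as.character(pm$groups[idx]))
}

#' Read a peak table and sample table into a profile matrix
#'
#' The peak table is a TSV (or CSV) with one row per compound: metadata
#' columns \code{compound_id, name, mass, metabolite, is_contaminant}
#' followed by one abundance column per sample. The sample table maps
#' \code{sample_id} to \code{group} (\code{case}/\code{control}) with
#' optional extra columns. Empty cells, \code{NA} and \code{0} all encode
#' "not detected" and become abundance 0.
#'
#' @param peak_table_path path to the peak table (TSV default; a
#'   \code{.csv} extension switches to comma separation).
#' @param sample_table_path path to the sample table.
#' @return A validated \code{profile_matrix}. Sample columns are matched to
#'   the sample table by id; extra sample-table columns are kept as an
#'   attribute \code{"sample_meta"}.
#' @seealso [write_profile_matrix()] for the inverse operation.
#' @export
read_profile_matrix <- function(peak_table_path, sample_table_path) {
  sep_of <- function(p) if (grepl("\\.csv$", p, ignore.case = TRUE)) "," else "\t"
  peaks <- utils::read.table(peak_table_path, header = TRUE, sep = sep_of(peak_table_path),
                             stringsAsFactors = FALSE, check.names = FALSE,
                             quote = "\"", comment.char = "")
  samples <- utils::read.table(sample_table_path, header = TRUE, sep = sep_of(sample_table_path),
                               stringsAsFactors = FALSE, check.names = FALSE,
                               quote = "\"", comment.char = "")
  meta_cols <- c("compound_id", "name", "mass", "metabolite", "is_contaminant")
  missing_meta <- setdiff(meta_cols, names(peaks))
  if (length(missing_meta))
    stop("peak table lacks metadata column(s): ", paste(missing_meta, collapse = ", "))
  if (!all(c("sample_id", "group") %in% names(samples)))
    stop("sample table must have 'sample_id' and 'group' columns")

  sample_cols <- setdiff(names(peaks), meta_cols)
  unknown <- setdiff(sample_cols, samples$sample_id)
  if (length(unknown))
    stop("peak-table sample column(s) absent from sample table: ",
         paste(unknown, collapse = ", "))
  absent <- setdiff(samples$sample_id, sample_cols)
  if (length(absent))
    stop("sample id(s) in sample table without a peak-table column: ",
         paste(absent, collapse = ", "))

  abund <- as.matrix(peaks[, samples$sample_id, drop = FALSE])
  pm <- profile_matrix(abund, peaks[, meta_cols], samples$sample_id, samples$group)
  extra <- setdiff(names(samples), c("sample_id", "group"))
  if (length(extra))
    attr(pm, "sample_meta") <- samples[, c("sample_id", extra), drop = FALSE]
  pm
}

#' Write a profile matrix to a peak table and sample table
#'
#' @param pm a \code{profile_matrix}.
#' @param peak_table_path,sample_table_path output TSV paths.
#' @return Invisibly, the two paths.
#' @export
write_profile_matrix <- function(pm, peak_table_path, sample_table_path) {
  stopifnot(inherits(pm, "profile_matrix"))
  peaks <- cbind(pm$compounds[, c("compound_id", "name", "mass", "metabolite",
                                  "is_contaminant")],
                 as.data.frame(pm$abundance, check.names = FALSE))
  utils::write.table(peaks, peak_table_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(data.frame(sample_id = pm$sample_ids,
                                group = as.character(pm$groups)),
                     sample_table_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(peak_table_path, sample_table_path))
}

#' Split samples into discovery and independent-test cohorts
#'
#' Allocates \code{discovery_size} samples to the discovery cohort in
#' proportion to group size, using largest-remainder rounding of
#' \code{group_n * discovery_size / total_n}, then draws a seeded simple
#' random sample within each group. The remaining samples form the test
#' cohort. With 63 cases and 61 controls and \code{discovery_size = 100}
#' this yields the 51/49 discovery and 12/12 test split.
#'
#' @param pm a \code{profile_matrix}.
#' @param discovery_size number of samples in the discovery cohort.
#' @param seed integer seed for the within-group draw.
#' @return An object of class \code{cohort_split}: list with
#'   \code{discovery_ids}, \code{test_ids}, \code{seed}.
#' @export
split_cohorts <- function(pm, discovery_size, seed) {
  stopifnot(inherits(pm, "profile_matrix"))
  n <- length(pm$sample_ids)
  if (discovery_size < 2 || discovery_size >= n)
    stop("'discovery_size' must be in [2, n_samples - 1]")
  counts <- table(pm$groups)
  quota <- as.numeric(counts) * discovery_size / n
  take <- floor(quota)
  rem <- discovery_size - sum(take)
  if (rem > 0) {
    # largest-remainder: hand leftover seats to largest fractional parts
    frac_order <- order(quota - take, decreasing = TRUE)
    take[frac_order[seq_len(rem)]] <- take[frac_order[seq_len(rem)]] + 1
  }
  names(take) <- names(counts)
  if (any(take == 0) || any(take == as.numeric(counts)))
    stop("allocation would leave a group empty in one cohort")

  discovery_ids <- character(0)
  with_seed(seed, {
    for (g in names(counts)) {
      ids_g <- pm$sample_ids[pm$groups == g]
      discovery_ids <- c(discovery_ids, sample(ids_g, take[[g]]))
    }
  })
  discovery_ids <- pm$sample_ids[pm$sample_ids %in% discovery_ids]
  structure(list(discovery_ids = discovery_ids,
                 test_ids = setdiff(pm$sample_ids, discovery_ids),
                 seed = seed),
            class = "cohort_split")
}

#' @export
print.cohort_split <- function(x, ...) {
  cat("cohort_split: ", length(x$discovery_ids), " discovery / ",
      length(x$test_ids), " test samples (seed ", x$seed, ")\n", sep = "")
  invisible(x)
}

# Run code under a temporary RNG state so callers' streams are untouched.
with_seed <- function(seed, code) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = env)
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(seed)
  eval.parent(substitute(code))
}
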