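#' Read an OTU count table
#'
#' Reads a tab-separated count table with OTUs as rows and samples as
#' columns. The first column must be named `otu_id`; every other column
#' header is taken as a sample identifier. Cells must be non-negative
#' integers: sequencing counts are integral by definition, so fractional
#' values are rejected rather than rounded.
#'
#' @param path Path to a TSV file.
#' @return An integer matrix with OTU ids as row names and sample ids as
#'   column names. Per-sample read depths are available via
#'   [sample_depths()].
#' @export
read_count_table <- function(path) {
  raw <- utils::read.delim(path, header = TRUE, sep = "\t",
                           colClasses = "character", check.names = FALSE,
                           stringsAsFactors = FALSE)
  if (ncol(raw) < 2L || nrow(raw) == 0L) {
    stop("count table '", path, "' has no samples or no OTUs", call. = FALSE)
  }
  if (names(raw)[1L] != "otu_id") {
    stop("first column must be named 'otu_id', found '", names(raw)[1L], "'",
         call. = FALSE)
  }
  otu_ids <- raw[[1L]]
  sample_ids <- names(raw)[-1L]
  if (anyDuplicated(otu_ids)) {
    stop("duplicated OTU ids: ",
         paste(unique(otu_ids[duplicated(otu_ids)]), collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(sample_ids)) {
    stop("duplicated sample ids: ",
         paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "),
         call. = FALSE)
  }
  counts <- matrix(0L, nrow = length(otu_ids), ncol = length(sample_ids),
                   dimnames = list(otu_ids, sample_ids))
  for (j in seq_along(sample_ids)) {
    col <- raw[[j + 1L]]
    num <- suppressWarnings(as.numeric(col))
    bad <- which(is.na(num) | num < 0 | num != floor(num))
    if (length(bad)) {
      stop("non-integer or negative count '", col[bad[1L]], "' for OTU '",
           otu_ids[bad[1L]], "' in sample '", sample_ids[j], "'",
           call. = FALSE)
    }
    counts[, j] <- as.integer(num)
  }
  validate_count_table(counts)
  counts
}

#' Per-sample read depths
#'
#' @param counts Count matrix (OTUs x samples).
#' @return Named numeric vector of column sums (sample read sums), the
#'   quantity whose log serves as the model offset.
#' @export
sample_depths <- function(counts) {
  validate_count_table(counts)
  colSums(counts)
}

validate_count_table <- function(counts) {
  stopifnot(is.matrix(counts))
  if (is.null(rownames(counts)) || is.null(colnames(counts))) {
    stop("count matrix must have OTU row names and sample column names",
         call. = FALSE)
  }
  if (anyDuplicated(rownames(counts)) || anyDuplicated(colnames(counts))) {
    stop("count matrix ids must be unique", call. = FALSE)
  }
  if (any(counts < 0) || any(counts != floor(counts)) || anyNA(counts)) {
    stop("counts must be non-negative integers with no missing values",
         call. = FALSE)
  }
  invisible(counts)
}

#' Read sample metadata describing the experimental design
#'
#' Expects a TSV with columns `sample`, `step`, `group`, `source_a`,
#' `source_b`, `frac_a`, `replicate`. Each sample belongs to Step 1 (a
#' removal treatment or the control C) or Step 2 (a self-mix R+R / C+C
#' or a coalescence mix R+C). `source_a`/`source_b` name the Step-1
#' parent communities and `frac_a` the mixing fraction of the first
#' (frac_b is its complement).
#'
#' @param path Path to a TSV file.
#' @return A `data.frame` with one row per sample and the columns above,
#'   `frac_b` added, validated for internal consistency.
#' @export
read_sample_metadata <- function(path) {
  md <- utils::read.delim(path, header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE)
  validate_design(as_design(md))
}

as_design <- function(md) {
  need <- c("sample", "step", "group", "source_a", "source_b", "frac_a",
            "replicate")
  missing <- setdiff(need, names(md))
  if (length(missing)) {
    stop("metadata lacks column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  md <- md[, c(need, setdiff(names(md), need)), drop = FALSE]
  md$step <- as.integer(md$step)
  md$frac_a <- as.numeric(md$frac_a)
  md$frac_b <- 1 - md$frac_a
  md$replicate <- as.integer(md$replicate)
  md
}

validate_design <- function(md) {
  if (!all(md$step %in% c(1L, 2L))) {
    stop("step must be 1 or 2; offending sample(s): ",
         paste(utils::head(md$sample[!md$step %in% c(1L, 2L)], 3L),
               collapse = ", "), call. = FALSE)
  }
  if (any(md$frac_a < 0 | md$frac_a > 1)) {
    stop("mixing fractions must lie in [0, 1]", call. = FALSE)
  }
  if (anyDuplicated(md$sample)) {
    stop("duplicated sample ids in metadata", call. = FALSE)
  }
  s1 <- md[md$step == 1L, , drop = FALSE]
  bad <- s1$source_a != s1$group | (s1$frac_b > 0 & s1$source_b != s1$group)
  if (any(bad)) {
    stop("Step-1 sample(s) with a source other than their own group: ",
         paste(utils::head(s1$sample[bad], 3L), collapse = ", "),
         call. = FALSE)
  }
  dup <- stats::aggregate(md$replicate, by = list(md$group, md$step),
                          FUN = function(r) anyDuplicated(r) > 0L)
  if (any(dup$x)) {
    stop("replicate indices must be unique within each group", call. = FALSE)
  }
  md
}

#' Mixing-fraction sources of a sample
#'
#' @param design Design data frame (see [read_sample_metadata()]).
#' @param sample Sample identifier.
#' @return Named numeric vector of source communities and mixing
#'   fractions summing to 1 (a self-mix collapses to a single entry).
#' @export
sample_sources <- function(design, sample) {
  row <- design[design$sample == sample, , drop = FALSE]
  if (nrow(row) != 1L) stop("unknown sample '", sample, "'", call. = FALSE)
  src <- c(row$frac_a, row$frac_b)
  names(src) <- c(row$source_a, row$source_b)
  src <- src[src > 0]
  tapply(src, names(src), sum)[unique(names(src))]
}

#' Read a rooted phylogenetic tree
#'
#' Reads a Newick tree with `ape`. Missing branch lengths are treated as
#' zero with a warning; duplicated leaf labels are an error. Coverage of
#' the OTU set is deliberately checked at metric time, not here, so a
#' tree can be shared across analyses that use OTU subsets.
#'
#' @param path Path to a Newick file.
#' @return An `ape` "phylo" object.
#' @export
read_newick <- function(path) {
  tree <- ape::read.tree(path)
  if (is.null(tree)) stop("could not parse Newick file '", path, "'",
                          call. = FALSE)
  if (anyDuplicated(tree$tip.label)) {
    stop("duplicated leaf labels: ",
         paste(unique(tree$tip.label[duplicated(tree$tip.label)]),
               collapse = ", "), call. = FALSE)
  }
  if (is.null(tree$edge.length)) {
    warning("tree has no branch lengths; treating all as 0")
    tree$edge.length <- rep(0, nrow(tree$edge))
  } else if (anyNA(tree$edge.length)) {
    warning("tree has missing branch lengths; treating them as 0")
    tree$edge.length[is.na(tree$edge.length)] <- 0
  }
  if (any(tree$edge.length < 0) || any(!is.finite(tree$edge.length))) {
    stop("branch lengths must be finite and non-negative", call. = FALSE)
  }
  tree
}

# 6 significant digits; p-values below 1e-4 in scientific notation
format_number <- function(x, p_value = FALSE) {
  out <- character(length(x))
  na <- is.na(x)
  out[na] <- "NA"
  if (p_value) {
    sci <- !na & x < 1e-4
    out[sci] <- sprintf("%.5e", x[sci])
    out[!na & !sci] <- sprintf("%.6g", x[!na & !sci])
  } else {
    out[!na] <- sprintf("%.6g", x[!na])
  }
  out
}

#' Write result tables and a JSON run summary
#'
#' Writes the tables produced by the pipeline as TSV files with fixed
#' schemas and deterministic row order (OTU id, then treatment label),
#' plus a `summary.json` capturing row counts per table and per
#' category. Repeated calls on identical inputs produce byte-identical
#' files (fixed sort order, fixed number formatting).
#'
#' @param tables Named list with any of `contrasts`, `classifications`,
#'   `diversity`, `summary` (the latter a list serialized to JSON).
#' @param out_dir Output directory, created if needed.
#' @return Invisibly, the paths written.
#' @export
write_results <- function(tables, out_dir) {
  allowed <- c("contrasts", "classifications", "diversity", "summary")
  unknown <- setdiff(names(tables), allowed)
  if (length(unknown)) {
    stop("unknown result table(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  if (!dir.exists(out_dir) &&
      !dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)) {
    stop("cannot create output directory '", out_dir, "'", call. = FALSE)
  }
  paths <- character(0)
  summary <- if (!is.null(tables$summary)) tables$summary else list()
  for (nm in intersect(c("contrasts", "classifications", "diversity"),
                       names(tables))) {
    df <- as.data.frame(tables[[nm]])
    ord <- do.call(order, lapply(intersect(c("otu_id", "treatment", "family",
                                             "level_a", "level_b", "sample",
                                             "metric"), names(df)),
                                 function(cl) df[[cl]]))
    if (length(ord)) df <- df[ord, , drop = FALSE]
    num <- vapply(df, is.numeric, logical(1)) &
      !vapply(df, is.integer, logical(1))
    for (cl in names(df)[num]) {
      df[[cl]] <- format_number(df[[cl]], p_value = grepl("^p_", cl))
    }
    path <- file.path(out_dir, paste0(nm, ".tsv"))
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, eol = "\n")
    summary[[paste0("n_", nm)]] <- nrow(df)
    if (nm == "classifications" && "category" %in% names(df)) {
      summary$category_counts <- as.list(table(df$category))
    }
    paths <- c(paths, path)
  }
  spath <- file.path(out_dir, "summary.json")
  jsonlite::write_json(summary, spath, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(c(paths, spath))
}

#' Write a count table to TSV
#'
#' Inverse of [read_count_table()]; round-trips exactly.
#'
#' @param counts Count matrix (OTUs x samples).
#' @param path Output path.
#' @export
write_count_table <- function(counts, path) {
  validate_count_table(counts)
  df <- data.frame(otu_id = rownames(counts), counts, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     eol = "\n")
  invisible(path)
}

#' Write sample metadata to TSV
#'
#' @param design Design data frame.
#' @param path Output path.
#' @export
write_sample_metadata <- function(design, path) {
  keep <- c("sample", "step", "group", "source_a", "source_b", "frac_a",
            "replicate")
  utils::write.table(design[, keep], path, sep = "\t", quote = FALSE,
                     row.names = FALSE, eol = "\n")
  invisible(path)
}
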