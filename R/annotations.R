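#' Protein-to-organelle annotation table
#'
#' Maps each protein to one or more organelle labels from the controlled
#' vocabulary (`EE`, `LE`, `Lysosome`, `ER`, `Golgi`, `Extracellular`,
#' `Other`) plus a boolean enzyme flag. Stands in for a strict GO
#' cellular-component localization annotation.
#'
#' @param protein_id character vector of protein ids (may repeat; repeated
#'   entries are merged by label union, enzyme flag OR-ed).
#' @param labels list of character vectors (one set of labels per entry) or a
#'   character vector of semicolon-separated labels.
#' @param enzyme logical vector.
#' @return Object of class `annotation_table`: data.frame with columns
#'   `protein_id`, `labels` (list column), `enzyme`.
#' @export
annotation_table <- function(protein_id, labels, enzyme = FALSE) {
  if (is.character(labels)) labels <- strsplit(labels, ";", fixed = TRUE)
  labels <- lapply(labels, function(l) unique(trimws(l)))
  bad <- setdiff(unique(unlist(labels)), ORGANELLE_LEVELS)
  if (length(bad))
    stop_data("unknown organelle label(s): %s (vocabulary: %s)",
              paste(bad, collapse = ", "),
              paste(ORGANELLE_LEVELS, collapse = ", "))
  if (any(lengths(labels) == 0))
    stop_data("every protein must carry at least one organelle label")
  enzyme <- rep_len(as.logical(enzyme), length(protein_id))
  df <- data.frame(protein_id = as.character(protein_id))
  df$labels <- labels
  df$enzyme <- enzyme
  if (anyDuplicated(df$protein_id)) {
    # merge rule: union of labels, OR of enzyme flags
    sp <- split(seq_len(nrow(df)), df$protein_id)
    df <- do.call(rbind, lapply(sp, function(idx) {
      out <- df[idx[1], , drop = FALSE]
      out$labels <- list(sort(unique(unlist(df$labels[idx]))))
      out$enzyme <- any(df$enzyme[idx])
      out
    }))
    rownames(df) <- NULL
  }
  class(df) <- c("annotation_table", "data.frame")
  df
}

#' Read an annotation table from TSV
#'
#' Expected dialect: `protein_id<TAB>labels<TAB>enzyme` with labels
#' semicolon-separated and enzyme in `TRUE/FALSE` (or `1/0`). A protein
#' listed on several lines gets the union of its labels.
#'
#' @param path file path.
#' @return An [annotation_table()].
#' @export
read_annotations <- function(path) {
  if (!file.exists(path)) stop_data("annotation file not found: %s", path)
  df <- read.delim(path, stringsAsFactors = FALSE)
  req <- c("protein_id", "labels", "enzyme")
  if (!all(req %in% names(df)))
    stop_data("annotation TSV must have columns: %s", paste(req, collapse = ", "))
  annotation_table(df$protein_id, df$labels, as.logical(df$enzyme))
}

#' Write an annotation table to TSV
#' @param annotations an [annotation_table()].
#' @param path output file path.
#' @return Invisibly, `path`.
#' @export
write_annotations <- function(annotations, path) {
  df <- data.frame(protein_id = annotations$protein_id,
                   labels = vapply(annotations$labels, paste,
                                   character(1), collapse = ";"),
                   enzyme = annotations$enzyme)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# labels for a set of protein ids; error if any id is unannotated
annotation_labels <- function(annotations, ids, context = "protein") {
  idx <- match(ids, annotations$protein_id)
  if (anyNA(idx))
    stop_data("unannotated %s(s): %s", context,
              paste(utils::head(ids[is.na(idx)], 5), collapse = ", "))
  annotations$labels[idx]
}
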