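# Cross-dataset agreement and the Type1/Type2/Mix consensus classification.
# Subtype labels are semantic (the DE-count rule), so no cluster-label
# alignment step is needed before comparing datasets.

check_labels_tbl <- function(labels) {
  need <- c("subject_id", "dataset_id", "label")
  missing <- setdiff(need, names(labels))
  if (length(missing)) {
    abort(paste0("labels need column(s): ", paste(missing, collapse = ", ")))
  }
  bad <- setdiff(unique(labels$label), c("Type1", "Type2"))
  if (length(bad)) {
    abort(paste0("per-dataset labels must be Type1/Type2; found: ",
                 paste(bad, collapse = ", ")))
  }
  invisible(labels)
}

#' Pairwise dataset agreement on shared subjects
#'
#' For every pair of datasets, the fraction of subjects labeled by both that
#' received the same subtype label.
#'
#' @param labels Long tibble with `subject_id`, `dataset_id`, `label`
#'   (Type1/Type2), e.g. from [subtype_labels()].
#' @return Tibble with `dataset_a`, `dataset_b`, `n_shared`, `match`.
#' @export
pairwise_match <- function(labels) {
  check_labels_tbl(labels)
  ds <- sort(unique(labels$dataset_id))
  if (length(ds) < 2L) abort("pairwise_match: need at least two datasets")
  wide <- tidyr::pivot_wider(labels, names_from = "dataset_id", values_from = "label")
  pairs <- utils::combn(ds, 2L, simplify = FALSE)
  purrr::map_dfr(pairs, function(pr) {
    a <- wide[[pr[1L]]]; b <- wide[[pr[2L]]]
    ok <- !is.na(a) & !is.na(b)
    if (!any(ok)) abort(sprintf("pairwise_match: no shared subjects between '%s' and '%s'", pr[1L], pr[2L]))
    tibble::tibble(dataset_a = pr[1L], dataset_b = pr[2L],
                   n_shared = sum(ok), match = mean(a[ok] == b[ok]))
  })
}

#' Consensus Type1/Type2/Mix classification of shared subjects
#'
#' A shared case subject is consensus Type 1 if labeled Type 1 in every
#' dataset, Type 2 if Type 2 in every dataset, and Mix otherwise (strict
#' unanimity). Subjects missing a label in any dataset are excluded with a
#' message.
#'
#' @param labels Long tibble (`subject_id`, `dataset_id`, `label`).
#' @return An `scz_consensus`: tibble of per-dataset labels plus `consensus`,
#'   with pairwise match fractions and group sizes as attributes
#'   (see [glance()]).
#' @export
consensus_classify <- function(labels) {
  check_labels_tbl(labels)
  ds <- sort(unique(labels$dataset_id))
  if (length(ds) < 2L) abort("consensus_classify: need at least two datasets")
  wide <- tidyr::pivot_wider(labels, names_from = "dataset_id", values_from = "label")
  wide <- wide[, c("subject_id", ds)]
  complete <- stats::complete.cases(wide)
  if (any(!complete)) {
    inform(sprintf("consensus_classify: excluded %d subject(s) unlabeled in some dataset", sum(!complete)))
  }
  wide <- wide[complete, , drop = FALSE]
  lab_mat <- as.matrix(wide[, ds, drop = FALSE])
  consensus <- apply(lab_mat, 1L, function(r) {
    if (all(r == "Type1")) "Type1" else if (all(r == "Type2")) "Type2" else "Mix"
  })
  out <- dplyr::mutate(wide, consensus = consensus)
  match_tbl <- pairwise_match(labels[labels$subject_id %in% wide$subject_id, ])
  structure(out, class = c("scz_consensus", class(out)),
            datasets = ds, match = match_tbl,
            sizes = c(Type1 = sum(consensus == "Type1"),
                      Type2 = sum(consensus == "Type2"),
                      Mix = sum(consensus == "Mix")))
}

#' @export
glance.scz_consensus <- function(x, ...) {
  sizes <- attr(x, "sizes")
  m <- attr(x, "match")
  tibble::tibble(n_subjects = nrow(x), n_type1 = sizes[["Type1"]],
                 n_type2 = sizes[["Type2"]], n_mix = sizes[["Mix"]],
                 min_pairwise_match = min(m$match), max_pairwise_match = max(m$match))
}

#' Agreement of a held-out dataset with the consensus
#'
#' Fraction of consensus Type 1/Type 2 subjects (Mix excluded) whose label
#' in a new dataset matches their consensus label — the check used to
#' validate a held-out fourth cohort against the consistently clustered
#' subjects.
#'
#' @param consensus An `scz_consensus`.
#' @param new_labels Tibble (`subject_id`, `label`) or named character
#'   vector of Type1/Type2 labels from the held-out dataset.
#' @return Fraction in \[0, 1\].
#' @export
holdout_agreement <- function(consensus, new_labels) {
  stopifnot(inherits(consensus, "scz_consensus"))
  if (!is.data.frame(new_labels)) {
    new_labels <- tibble::tibble(subject_id = names(new_labels), label = unname(new_labels))
  }
  core <- consensus[consensus$consensus %in% c("Type1", "Type2"), c("subject_id", "consensus")]
  merged <- dplyr::inner_join(core, new_labels, by = "subject_id")
  if (nrow(merged) == 0L) abort("holdout_agreement: no overlap with consensus Type1/Type2 subjects")
  mean(merged$consensus == merged$label)
}
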