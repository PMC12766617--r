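#' Patient-level train/validation/test split
#'
#' Disjoint subject-level partition at the given ratios (default 80:10:10)
#' with largest-remainder rounding; deterministic for a fixed seed. Splitting
#' at the patient level prevents data leakage between sets.
#'
#' @param subject_ids character or integer vector of unique subject ids
#'   (at least 10).
#' @param seed split seed.
#' @param ratios length-3 positive weights for (train, validation, test).
#' @return List \code{train}, \code{val}, \code{test} of subject ids.
#' @export
split_patients <- function(subject_ids, seed = 1, ratios = c(0.8, 0.1, 0.1)) {
  stop_if_not(length(subject_ids) >= 10, "need at least 10 subjects to split")
  stop_if_not(!anyDuplicated(subject_ids), "subject ids must be unique")
  stop_if_not(length(ratios) == 3 && all(ratios > 0), "ratios must be 3 positive weights")
  ratios <- ratios / sum(ratios)
  n <- length(subject_ids)
  raw <- n * ratios
  sizes <- floor(raw)
  rem <- n - sum(sizes)
  if (rem > 0) {
    extra <- order(raw - sizes, decreasing = TRUE)[seq_len(rem)]
    sizes[extra] <- sizes[extra] + 1
  }
  perm <- with_seed(seed, sample(subject_ids))
  list(train = perm[seq_len(sizes[1])],
       val = perm[sizes[1] + seq_len(sizes[2])],
       test = perm[sizes[1] + sizes[2] + seq_len(sizes[3])])
}
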