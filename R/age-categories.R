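#' Age categories of adult female elephants
#'
#' Adult females are classed into four ordered categories: young adults
#' (over 12 and under 20 years old), prime adults (20-35), mature adults
#' (over 35) and the matriarch, the oldest or most dominant female of a
#' core group. Ranks run from 1 (young adult) to 4 (matriarch) and are the
#' ordering used for age-targeted deletions and for the age effect on
#' association probabilities.
#'
#' @return A tibble with columns `label` (character), `abbrev` (one of
#'   `"Y"`, `"P"`, `"M"`, `"G"`) and `rank` (integer 1-4).
#' @examples
#' age_categories()
#' @export
age_categories <- function() {
  tibble(
    label  = c("young_adult", "prime_adult", "mature_adult", "matriarch"),
    abbrev = c("Y", "P", "M", "G"),
    rank   = 1:4
  )
}

age_levels <- function() age_categories()$label

#' Rank of an age category
#'
#' @param x Character vector of age-category labels
#'   (`"young_adult"`, `"prime_adult"`, `"mature_adult"`, `"matriarch"`).
#' @return Integer vector of ranks (1 = young adult ... 4 = matriarch).
#' @examples
#' age_rank(c("matriarch", "young_adult"))
#' @export
age_rank <- function(x) {
  r <- match(as.character(x), age_levels())
  if (anyNA(r) && !anyNA(x)) {
    bad <- setdiff(unique(as.character(x)), age_levels())
    abort(sprintf("Unknown age category: %s", paste(bad, collapse = ", ")))
  }
  r
}

age_abbrev <- function(x) age_categories()$abbrev[age_rank(x)]

# canonical unordered age-pair label, younger rank first, e.g. "Y-G"
age_pair_label <- function(a, b) {
  ra <- age_rank(a)
  rb <- age_rank(b)
  ab <- age_categories()$abbrev
  paste(ab[pmin(ra, rb)], ab[pmax(ra, rb)], sep = "-")
}
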