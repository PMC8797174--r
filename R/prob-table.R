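#' Default association-probability table
#'
#' The network-formation simulator draws each dyad's per-time-step
#' association probability from a triangular distribution whose (min, mode,
#' max) depend on the dyad's kinship tier and unordered age-category pair.
#' The empirical per-tier/per-age ranges are not published, so the values
#' here are package defaults chosen to satisfy the qualitative structure of
#' the reference population:
#'
#' * for any fixed age pair, the (min, mode, max) triple is componentwise
#'   ordered core >= bond >= clan >= nonkin (individuals associate most
#'   within their core group, then bond, then clan, and least with non-kin);
#' * within a tier, entries increase weakly with the partners' age ranks
#'   (individuals are slightly more likely to associate with conspecifics of
#'   older categories).
#'
#' The age effect is a linear bump of `age_bump` per rank step above the
#' youngest pair, added to min, mode and max alike.
#'
#' @param core,bond,clan,nonkin Length-3 numeric vectors `(min, mode, max)`
#'   of the base triangular parameters per tier (for a young-young dyad).
#' @param age_bump Increment added per unit of `(rank_a + rank_b - 2)`.
#' @return A probability table: tibble with columns `tier`, `age_a`, `age_b`
#'   (labels, younger first), `min`, `mode`, `max`, one row per tier x
#'   unordered age pair (4 x 10 = 40 rows), validated by
#'   [validate_probability_table()].
#' @examples
#' tab <- default_probability_table()
#' @export
default_probability_table <- function(core   = c(0.30, 0.50, 0.80),
                                      bond   = c(0.060, 0.120, 0.220),
                                      clan   = c(0.020, 0.050, 0.100),
                                      nonkin = c(0.004, 0.015, 0.040),
                                      age_bump = 0.005) {
  base <- list(core = core, bond = bond, clan = clan, nonkin = nonkin)
  ages <- age_categories()
  pairs <- utils::combn(4, 2)
  ia <- c(1:4, pairs[1, ])
  ib <- c(1:4, pairs[2, ])

  out <- purrr::map_dfr(kinship_levels(), function(tr) {
    b <- base[[tr]]
    tibble(
      tier = tr,
      age_a = ages$label[ia],
      age_b = ages$label[ib],
      min  = pmin(1, b[1] + age_bump * (ia + ib - 2)),
      mode = pmin(1, b[2] + age_bump * (ia + ib - 2)),
      max  = pmin(1, b[3] + age_bump * (ia + ib - 2))
    )
  })
  validate_probability_table(out)
}

#' Validate an association-probability table
#'
#' Checks completeness (all 4 tiers x 10 unordered age pairs), that every
#' entry satisfies `0 <= min <= mode <= max <= 1`, the componentwise tier
#' ordering core >= bond >= clan >= nonkin for each fixed age pair, and weak
#' monotonicity in the partners' age ranks within each tier.
#'
#' @param table Probability table tibble (columns `tier`, `age_a`, `age_b`,
#'   `min`, `mode`, `max`).
#' @return The table, with a canonical `age_pair` key column, invisibly
#'   unchanged otherwise.
#' @export
validate_probability_table <- function(table) {
  table <- as_tibble(table)
  required <- c("tier", "age_a", "age_b", "min", "mode", "max")
  missing <- setdiff(required, names(table))
  if (length(missing)) {
    abort(sprintf("Probability table is missing columns: %s",
                  paste(missing, collapse = ", ")))
  }
  table$age_pair <- age_pair_label(table$age_a, table$age_b)
  rank_pairs <- which(upper.tri(matrix(0, 4, 4), diag = TRUE), arr.ind = TRUE)
  pair_labels <- age_pair_label(
    age_levels()[rank_pairs[, "row"]], age_levels()[rank_pairs[, "col"]]
  )
  want <- tidyr::expand_grid(tier = kinship_levels(), age_pair = pair_labels)
  have <- paste(table$tier, table$age_pair)
  gaps <- setdiff(paste(want$tier, want$age_pair), have)
  if (length(gaps)) {
    abort(sprintf("Probability table is missing entries: %s",
                  paste(gaps, collapse = "; ")))
  }
  if (anyDuplicated(have)) abort("Probability table has duplicate (tier, age pair) entries.")

  bad <- table$min < 0 | table$min > table$mode | table$mode > table$max | table$max > 1
  if (any(bad)) {
    abort(sprintf("Entries violate 0 <= min <= mode <= max <= 1: %s",
                  paste(have[bad], collapse = "; ")))
  }

  wide <- table |>
    select("tier", "age_pair", "min", "mode", "max") |>
    tidyr::pivot_wider(names_from = "tier", values_from = c("min", "mode", "max"))
  for (p in c("min", "mode", "max")) {
    m <- as.matrix(wide[paste(p, kinship_levels(), sep = "_")])
    if (any(m[, 1] < m[, 2] | m[, 2] < m[, 3] | m[, 3] < m[, 4])) {
      abort("Tier ordering core >= bond >= clan >= nonkin violated.")
    }
  }

  # weak monotonicity in age rank within each tier, componentwise
  ra <- age_rank(table$age_a)
  rb <- age_rank(table$age_b)
  lo <- pmin(ra, rb)
  hi <- pmax(ra, rb)
  for (tr in kinship_levels()) {
    rows <- which(table$tier == tr)
    for (p in c("min", "mode", "max")) {
      v <- matrix(NA_real_, 4, 4)
      v[cbind(lo[rows], hi[rows])] <- table[[p]][rows]
      for (i in 1:4) for (j in i:4) {
        if (j < 4 && v[i, j] > v[i, j + 1] + 1e-12) {
          abort(sprintf("Tier %s: entries must weakly increase with age rank.", tr))
        }
        if (i < j && v[i, j] > v[i + 1, j] + 1e-12) {
          abort(sprintf("Tier %s: entries must weakly increase with age rank.", tr))
        }
      }
    }
  }
  table
}

# per-dyad (min, mode, max) lookup; errors naming any missing (tier, pair)
lookup_probability <- function(table, tier, age_a, age_b) {
  table <- validate_probability_table(table)
  key <- paste(tier, age_pair_label(age_a, age_b))
  idx <- match(key, paste(table$tier, table$age_pair))
  if (anyNA(idx)) {
    abort(sprintf("No probability-table entry for: %s",
                  paste(unique(key[is.na(idx)]), collapse = "; ")))
  }
  tibble(min = table$min[idx], mode = table$mode[idx], max = table$max[idx])
}
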