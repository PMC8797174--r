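#' Sighting-count tables
#'
#' Container for the two tiers of raw association records that the
#' empirical assembly consumes:
#'
#' * `within`: per core-group dyad, `x` (sightings of the pair together),
#'   `d` (sightings at which neither member was seen) and `n_g` (total
#'   observations of the group), with `x + d <= n_g`;
#' * `between`: per core-group pair, `n_ab` (co-sightings of the two
#'   groups), `n_a_only` and `n_b_only` (sightings of each group without
#'   the other).
#'
#' @param within Tibble with columns `group`, `id_a`, `id_b`, `x`, `d`, `n_g`.
#' @param between Tibble with columns `group_a`, `group_b`, `n_ab`,
#'   `n_a_only`, `n_b_only`.
#' @return A list of class `"sighting_counts"`.
#' @export
sighting_counts <- function(within, between) {
  within <- as_tibble(within)
  between <- as_tibble(between)
  need_w <- c("group", "id_a", "id_b", "x", "d", "n_g")
  need_b <- c("group_a", "group_b", "n_ab", "n_a_only", "n_b_only")
  if (!all(need_w %in% names(within))) {
    abort(sprintf("`within` needs columns: %s", paste(need_w, collapse = ", ")))
  }
  if (!all(need_b %in% names(between))) {
    abort(sprintf("`between` needs columns: %s", paste(need_b, collapse = ", ")))
  }
  if (any(within$x < 0 | within$d < 0 | within$n_g < 0) ||
      any(within$x + within$d > within$n_g)) {
    abort("Within-group counts must satisfy 0 <= x, 0 <= d, x + d <= n_g.")
  }
  if (any(between$n_ab < 0 | between$n_a_only < 0 | between$n_b_only < 0)) {
    abort("Between-group counts must be nonnegative.")
  }
  if (anyDuplicated(pair_key(within$id_a, within$id_b))) {
    abort("Duplicate within-group dyads.")
  }
  if (anyDuplicated(pair_key(between$group_a, between$group_b))) {
    abort("Duplicate group pairs.")
  }
  structure(list(within = within, between = between), class = "sighting_counts")
}

as_sighting_counts <- function(x) {
  if (inherits(x, "sighting_counts")) return(x)
  if (is.list(x) && all(c("within", "between") %in% names(x))) {
    return(sighting_counts(x$within, x$between))
  }
  abort("`counts` must be a sighting_counts object (or a list with $within and $between).")
}

#' @export
print.sighting_counts <- function(x, ...) {
  cat(sprintf("<sighting_counts>  %d within-group dyads, %d group pairs\n",
              nrow(x$within), nrow(x$between)))
  invisible(x)
}

#' Simulate sighting records for a virtual population
#'
#' Emulates the field protocol that produces within-group and between-group
#' sighting counts, so that the empirical assembly pipeline can be exercised
#' on populations with known structure. The raw field records behind the
#' reference population are unpublished; this generator is package plumbing
#' with documented, configurable probabilities -- not an estimate of the
#' field data.
#'
#' For each core group, `n_events` potential observation events are
#' simulated; the group is sighted at each event with probability
#' `group_prob`. At each sighting every member is present independently with
#' its presence probability (by default the mean of the core-tier triangular
#' entry for its age category paired with itself; a scalar `presence_prob`
#' overrides this). Dyadic tallies accumulate `x` (both present) and `d`
#' (neither present) against `n_g` (group sightings). For each pair of core
#' groups, events with any sighting of the pair occur with probability
#' `group_prob`; given a sighting, the two groups are seen together with the
#' pair's co-sighting probability (by default a per-tier constant from
#' `together_prob`), otherwise one of the two groups alone with equal
#' probability -- so the expected group-pair fraction equals the configured
#' co-sighting probability.
#'
#' @param pop Population roster.
#' @param table Association-probability table used to derive default
#'   presence probabilities.
#' @param n_events Number of potential observation events per group and per
#'   group pair (>= 1).
#' @param seed Optional integer seed.
#' @param group_prob Probability that a group (or group pair) is sighted at
#'   an event.
#' @param presence_prob Optional scalar in `[0, 1]` forcing every member's
#'   presence probability.
#' @param together_prob Named list of per-tier co-sighting probabilities for
#'   group pairs (`bond`, `clan`, `nonkin`).
#' @return A [sighting_counts()] object.
#' @examples
#' pop <- generate_population(population_config(1, 1, 2), seed = 1)
#' counts <- generate_sightings(pop, default_probability_table(), 50, seed = 2)
#' @export
generate_sightings <- function(pop, table = default_probability_table(),
                               n_events = 200, seed = NULL,
                               group_prob = 0.8, presence_prob = NULL,
                               together_prob = list(bond = 0.15, clan = 0.08,
                                                    nonkin = 0.03)) {
  pop <- validate_population(pop)
  if (nrow(pop) == 0) abort("Empty population.")
  stopifnot_scalar_count(n_events, "n_events", min = 1)
  table <- validate_probability_table(table)

  with_seed_if(seed, {
    # per-individual presence probability
    if (is.null(presence_prob)) {
      ent <- lookup_probability(table, "core", pop$age_category, pop$age_category)
      p_present <- (ent$min + ent$mode + ent$max) / 3
    } else {
      if (presence_prob < 0 || presence_prob > 1) abort("`presence_prob` must be in [0, 1].")
      p_present <- rep(presence_prob, nrow(pop))
    }
    names(p_present) <- pop$id

    within <- purrr::map_dfr(split(pop, pop$core_id), function(grp) {
      sighted <- stats::runif(n_events) < group_prob
      n_g <- sum(sighted)
      members <- grp$id
      if (length(members) < 2 || n_g == 0) {
        present <- matrix(FALSE, 0, length(members))
      } else {
        present <- matrix(
          stats::runif(n_g * length(members)) < rep(p_present[members], each = n_g),
          nrow = n_g
        )
      }
      idx <- utils::combn(length(members), 2)
      tibble(
        group = grp$core_id[1],
        id_a = members[idx[1, ]],
        id_b = members[idx[2, ]],
        x = vapply(seq_len(ncol(idx)), function(k) {
          sum(present[, idx[1, k]] & present[, idx[2, k]])
        }, numeric(1)),
        d = vapply(seq_len(ncol(idx)), function(k) {
          sum(!present[, idx[1, k]] & !present[, idx[2, k]])
        }, numeric(1)),
        n_g = n_g
      )
    })

    gp <- group_pair_tier(pop)
    between <- gp |>
      mutate(
        p_together = purrr::map_dbl(.data$tier, ~ together_prob[[.x]]),
        n_sighted = stats::rbinom(n(), n_events, group_prob),
        n_ab = stats::rbinom(n(), .data$n_sighted, .data$p_together),
        n_alone = .data$n_sighted - .data$n_ab,
        n_a_only = stats::rbinom(n(), .data$n_alone, 0.5),
        n_b_only = .data$n_alone - .data$n_a_only
      ) |>
      select("group_a", "group_b", "n_ab", "n_a_only", "n_b_only")

    sighting_counts(within, between)
  })
}
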