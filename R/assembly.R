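#' Within-core-group association index
#'
#' The dyadic association index between two members of the same core group:
#' the number of sightings of the pair together, divided by the number of
#' group observations at which the dyad was observable (total group
#' observations minus the sightings at which neither member was seen),
#'
#' \deqn{AI_{ij} = x_{ij} / (n_G - d_{ij}).}
#'
#' @param x Times the two individuals were seen together (count).
#' @param d Times neither individual was seen (count).
#' @param n_g Total number of observations of their core group (count).
#' @return Association index in `[0, 1]` (vectorized).
#' @examples
#' within_group_ai(5, 2, 10) # 0.625
#' @export
within_group_ai <- function(x, d, n_g) {
  if (any(x < 0 | d < 0 | n_g < 0)) abort("Counts must be nonnegative.")
  if (any(n_g <= d)) {
    abort("Undefined association index: the dyad was never observable (n_g <= d).")
  }
  if (any(x + d > n_g)) abort("Counts must satisfy x + d <= n_g.")
  x / (n_g - d)
}

#' Gregariousness of an individual within its core group
#'
#' The mean of an individual's within-core-group association indices over
#' the dyads that involve it (group size minus one dyads). Falls in
#' `[0, 1]` and equals 1 for an individual seen with every groupmate at
#' every observable sighting. Used as the individual factor when projecting
#' associations across core groups.
#'
#' @param ai Numeric vector of the individual's within-group association
#'   indices (one per groupmate).
#' @return Gregariousness score in `[0, 1]`.
#' @examples
#' gregariousness(c(0.2, 0.6)) # 0.4
#' @export
gregariousness <- function(ai) {
  if (length(ai) < 1) {
    abort("Gregariousness is undefined in a singleton core group.")
  }
  if (any(ai < 0 | ai > 1)) abort("Association indices must lie in [0, 1].")
  sum(ai) / length(ai)
}

#' Fraction of sightings at which two core groups were seen together
#'
#' \deqn{f_{G,B} = n_{G,B} / (n_G + n_B + n_{G,B})}
#' where \eqn{n_{G,B}} counts co-sightings of the two groups and
#' \eqn{n_G}, \eqn{n_B} count sightings of each group without the other.
#'
#' @param n_gb Co-sightings of groups G and B (count).
#' @param n_g_only Sightings of G without B (count).
#' @param n_b_only Sightings of B without G (count).
#' @return Fraction in `[0, 1]` (vectorized).
#' @examples
#' group_pair_fraction(10, 20, 20) # 0.2
#' @export
group_pair_fraction <- function(n_gb, n_g_only, n_b_only) {
  if (any(n_gb < 0 | n_g_only < 0 | n_b_only < 0)) abort("Counts must be nonnegative.")
  denom <- n_g_only + n_b_only + n_gb
  if (any(denom == 0)) {
    abort("Undefined group-pair fraction: the two groups were never sighted.")
  }
  n_gb / denom
}

#' Cross-core-group association weight
#'
#' Proxy association index between individuals of two different core
#' groups: the product of the two individuals' gregariousness scores and
#' the fraction of sightings at which their groups were seen together,
#' \deqn{p(i_G, a_B) = f_{i_G} \times f_{a_B} \times f_{G,B}.}
#'
#' @param f_i,f_a Gregariousness scores of the two individuals.
#' @param f_gb Group-pair co-sighting fraction.
#' @return Association index in `[0, 1]` (vectorized).
#' @examples
#' cross_group_weight(0.5, 0.4, 0.2) # 0.04
#' @export
cross_group_weight <- function(f_i, f_a, f_gb) {
  vals <- c(f_i, f_a, f_gb)
  if (any(vals < 0 | vals > 1)) abort("All factors must lie in [0, 1].")
  f_i * f_a * f_gb
}

#' Assemble the population-wide association network from sighting counts
#'
#' Builds the symmetric weighted network over all individuals of a
#' multi-tier population: within-core-group edges are the dyadic association
#' indices from the within-group counts ([within_group_ai()]); edges between
#' individuals of different core groups are the gregariousness-times-
#' group-fraction products ([cross_group_weight()], using
#' [gregariousness()] and [group_pair_fraction()]). Dyads with weight zero
#' are absent edges. All weights lie in `[0, 1]`.
#'
#' @param counts A [sighting_counts()] object (or a list with tibbles
#'   `within` and `between` in the same dialect).
#' @param pop Population roster covering every individual referenced in the
#'   counts.
#' @param id Optional network identifier.
#' @return An [assoc_network()] whose node set equals the roster.
#' @export
assemble_network <- function(counts, pop, id = NULL) {
  counts <- as_sighting_counts(counts)
  pop <- validate_population(pop)

  # ---- coverage checks -----------------------------------------------------
  dy <- dyad_table(pop)
  core_dyads <- dy[dy$tier == "core", ]
  have_within <- pair_key(counts$within$id_a, counts$within$id_b)
  need_within <- pair_key(core_dyads$id_a, core_dyads$id_b)
  gaps <- setdiff(need_within, have_within)
  if (length(gaps)) {
    abort(sprintf("Missing within-group counts for dyads: %s",
                  paste(gaps, collapse = ", ")))
  }
  gp <- group_pair_tier(pop)
  have_between <- pair_key(counts$between$group_a, counts$between$group_b)
  need_between <- pair_key(gp$group_a, gp$group_b)
  gaps <- setdiff(need_between, have_between)
  if (length(gaps)) {
    abort(sprintf("Missing between-group counts for group pairs: %s",
                  paste(gaps, collapse = ", ")))
  }

  # ---- within-core edges (association indices) -----------------------------
  win <- counts$within |>
    semi_join(
      tibble(id_a = c(core_dyads$id_a, core_dyads$id_b),
             id_b = c(core_dyads$id_b, core_dyads$id_a)),
      by = c("id_a", "id_b")
    ) |>
    mutate(ai = within_group_ai(.data$x, .data$d, .data$n_g))

  # ---- gregariousness per individual ---------------------------------------
  greg <- bind_rows(
    select(win, id = "id_a", "ai"),
    select(win, id = "id_b", "ai")
  ) |>
    group_by(.data$id) |>
    summarise(f = gregariousness(.data$ai), .groups = "drop")
  if (!all(pop$id %in% greg$id)) {
    abort(sprintf("No within-group dyads found for: %s",
                  paste(setdiff(pop$id, greg$id), collapse = ", ")))
  }

  # ---- group-pair fractions ------------------------------------------------
  frac <- counts$between |>
    mutate(
      key = pair_key(.data$group_a, .data$group_b),
      f_gb = group_pair_fraction(.data$n_ab, .data$n_a_only, .data$n_b_only)
    )

  # ---- cross-core edges ----------------------------------------------------
  cross <- dy[dy$tier != "core", ] |>
    left_join(select(greg, id_a = "id", f_a = "f"), by = "id_a") |>
    left_join(select(greg, id_b = "id", f_b = "f"), by = "id_b") |>
    mutate(key = pair_key(.data$core_a, .data$core_b)) |>
    left_join(select(frac, "key", "f_gb"), by = "key") |>
    mutate(weight = cross_group_weight(.data$f_a, .data$f_b, .data$f_gb))

  edges <- bind_rows(
    select(win, "id_a", "id_b", weight = "ai"),
    select(cross, "id_a", "id_b", "weight")
  ) |>
    filter(.data$weight > 0)

  assoc_network(edges, roster = pop, id = id %||% "assembled")
}
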