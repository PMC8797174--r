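#' Read and write population rosters
#'
#' Plain-CSV roster dialect: columns `id`, `age_category`, `core_id`,
#' `bond_id`, `clan_id`. Reading validates the multi-tier invariants.
#'
#' @param pop Population roster tibble.
#' @param path File path.
#' @return `read_population()` returns a validated roster tibble;
#'   `write_population()` returns `path` invisibly.
#' @export
write_population <- function(pop, path) {
  readr::write_csv(validate_population(pop), path)
  invisible(path)
}

#' @rdname write_population
#' @export
read_population <- function(path) {
  validate_population(readr::read_csv(path, show_col_types = FALSE,
                                      col_types = readr::cols(.default = "c")))
}

#' Read and write association-probability tables
#'
#' CSV dialect: columns `tier`, `age_a`, `age_b`, `min`, `mode`, `max`.
#' Reading validates completeness and the ordering invariants.
#'
#' @param table Probability table tibble.
#' @param path File path.
#' @return `read_probability_table()` returns a validated table;
#'   `write_probability_table()` returns `path` invisibly.
#' @export
write_probability_table <- function(table, path) {
  readr::write_csv(
    select(validate_probability_table(table),
           "tier", "age_a", "age_b", "min", "mode", "max"),
    path
  )
  invisible(path)
}

#' @rdname write_probability_table
#' @export
read_probability_table <- function(path) {
  validate_probability_table(readr::read_csv(
    path, show_col_types = FALSE,
    col_types = readr::cols(min = "d", mode = "d", max = "d", .default = "c")
  ))
}

#' Read and write sighting-count tables
#'
#' Two CSVs sharing a stem: `<stem>_within.csv` (columns `group`, `id_a`,
#' `id_b`, `x`, `d`, `n_g`) and `<stem>_between.csv` (columns `group_a`,
#' `group_b`, `n_ab`, `n_a_only`, `n_b_only`).
#'
#' @param counts A [sighting_counts()] object.
#' @param stem Path stem (without the `_within.csv` / `_between.csv`
#'   suffixes).
#' @return `read_sightings()` returns a [sighting_counts()];
#'   `write_sightings()` returns `stem` invisibly.
#' @export
write_sightings <- function(counts, stem) {
  counts <- as_sighting_counts(counts)
  readr::write_csv(counts$within, paste0(stem, "_within.csv"))
  readr::write_csv(counts$between, paste0(stem, "_between.csv"))
  invisible(stem)
}

#' @rdname write_sightings
#' @export
read_sightings <- function(stem) {
  sighting_counts(
    readr::read_csv(paste0(stem, "_within.csv"), show_col_types = FALSE),
    readr::read_csv(paste0(stem, "_between.csv"), show_col_types = FALSE)
  )
}

#' Read and write weighted networks
#'
#' Two dialects: an edge-list CSV (`id_a`, `id_b`, `weight`; the canonical
#' interchange format) and GraphML with node attributes (`age_category`,
#' `core_id`, `bond_id`, `clan_id`) for external viewers. Readers validate
#' rather than repair: self-loops, duplicate edges, nonpositive weights and
#' (for GraphML) missing node attributes are rejected.
#'
#' @param net An [assoc_network()].
#' @param path File path; the dialect is inferred from the extension
#'   (`.csv` or `.graphml`) unless `format` is given.
#' @param format `"csv"` or `"graphml"`.
#' @param roster Optional roster attached on reading a CSV edge list (CSV
#'   carries no node attributes; isolated nodes survive a round trip only
#'   through the roster).
#' @return `read_network()` returns an [assoc_network()];
#'   `write_network()` returns `path` invisibly.
#' @export
write_network <- function(net, path, format = NULL) {
  stopifnot(inherits(net, "assoc_network"))
  format <- format %||% infer_format(path)
  if (format == "csv") {
    readr::write_csv(net$edges, path)
  } else {
    igraph::write_graph(as_igraph(net), path, format = "graphml")
  }
  invisible(path)
}

#' @rdname write_network
#' @export
read_network <- function(path, format = NULL, roster = NULL) {
  format <- format %||% infer_format(path)
  if (format == "csv") {
    edges <- readr::read_csv(path, show_col_types = FALSE,
                             col_types = readr::cols(weight = "d", .default = "c"))
    assoc_network(edges, roster = roster, id = tools::file_path_sans_ext(basename(path)))
  } else {
    g <- igraph::read_graph(path, format = "graphml")
    attrs <- igraph::vertex_attr_names(g)
    needed <- c("age_category", "core_id", "bond_id", "clan_id")
    missing <- setdiff(needed, attrs)
    if (length(missing)) {
      abort(sprintf("GraphML is missing node attributes: %s",
                    paste(missing, collapse = ", ")))
    }
    el <- igraph::as_data_frame(g, what = "edges")
    vs <- igraph::as_data_frame(g, what = "vertices")
    assoc_network(
      tibble(id_a = el$from, id_b = el$to, weight = el$weight),
      roster = tibble(
        id = vs$name, age_category = vs$age_category,
        core_id = vs$core_id, bond_id = vs$bond_id, clan_id = vs$clan_id
      ),
      id = tools::file_path_sans_ext(basename(path))
    )
  }
}

infer_format <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "csv") return("csv")
  if (ext == "graphml") return("graphml")
  abort("Cannot infer format: use a .csv or .graphml path or pass `format`.")
}

#' Read a flat key-value run configuration
#'
#' YAML-dialect configuration for population generation and simulation runs
#' (population composition, number of events/steps, seeds). Unknown keys are
#' kept verbatim so stage-specific settings can share one file.
#'
#' @param path Path to the YAML file.
#' @return Named list.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (!is.list(cfg)) abort("Configuration must be a key-value mapping.")
  cfg
}

#' Build and write a run manifest
#'
#' Records what produced a set of artifacts: the configuration snapshot, the
#' seeds, the package version, MD5 hashes of the listed files and a
#' timestamp. Re-running a stage with the recorded config and seed
#' reproduces the hashed outputs bit for bit.
#'
#' @param config Named list (configuration snapshot).
#' @param seed Integer seed(s) of the run.
#' @param files Character vector of artifact paths to hash.
#' @param path Optional path; when given, the manifest is also written as
#'   JSON.
#' @return The manifest as a named list (invisibly when written).
#' @export
run_manifest <- function(config = list(), seed = NULL, files = character(),
                         path = NULL) {
  manifest <- list(
    package = "poachnet",
    version = as.character(utils::packageVersion("poachnet")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    seed = seed,
    config = config,
    files = if (length(files)) {
      tibble(path = files, md5 = unname(tools::md5sum(files)))
    } else {
      tibble(path = character(), md5 = character())
    }
  )
  if (!is.null(path)) {
    jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
    return(invisible(manifest))
  }
  manifest
}
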