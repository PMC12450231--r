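# Shared fixture builders. Everything is generated in code; no stored data.

small_config <- function(...) {
  defaults <- list(width = 40, height = 20, n_attractors_per_region = 2,
                   ticks = 60, n_agents = 6)
  do.call(coop_config, utils::modifyList(defaults, list(...)))
}

tiny_grid <- function(width = 40, height = 20, n = 2, seed = 42, ...) {
  synthetic_landscape(width, height, n_attractors_per_region = n,
                      seed = seed, ...)
}

# hand-built agent table with sensible defaults, vectorized over any field
new_agents <- function(n = 1, x = 5, y = 5, origin = "TianShan",
                       energy = 100, body_temp = 37, age = 30,
                       trait = 1L, knows_path = FALSE, target = NA_integer_,
                       alive = TRUE) {
  tibble::tibble(
    id = seq_len(n),
    x = rep_len(as.numeric(x), n), y = rep_len(as.numeric(y), n),
    origin = rep_len(origin, n),
    energy = rep_len(as.numeric(energy), n),
    body_temp = rep_len(as.numeric(body_temp), n),
    age = rep_len(as.numeric(age), n),
    trait = rep_len(as.integer(trait), n),
    knows_path = rep_len(knows_path, n),
    target = rep_len(as.integer(target), n),
    dest_x = NA_real_, dest_y = NA_real_,
    low_res_ticks = 0L,
    alive = rep_len(alive, n),
    death_cause = NA_character_
  )
}

new_attractors <- function(x, y, region = NULL, store = 500, active = TRUE,
                           grid = NULL) {
  n <- length(x)
  if (is.null(region)) {
    region <- if (is.null(grid)) rep("TianShan", n) else region_of(grid, x)
  }
  tibble::tibble(
    id = seq_len(n), x = as.numeric(x), y = as.numeric(y),
    region = rep_len(region, n), store = rep_len(as.numeric(store), n),
    active = rep_len(active, n), founded_tick = 0L,
    collapsed_tick = NA_integer_
  )
}

write_asc <- function(values, ncols, nrows, nodata = -9999,
                      path = tempfile(fileext = ".asc")) {
  header <- c(
    paste("ncols", ncols), paste("nrows", nrows),
    "xllcorner 0", "yllcorner 0", "cellsize 1",
    paste("NODATA_value", nodata)
  )
  writeLines(c(header, values), path)
  path
}

write_sites_csv <- function(df, path = tempfile(fileext = ".csv")) {
  readr::write_csv(df, path)
  path
}

# minimum pairwise distance (km) among attractors whose activity windows
# overlap; brute force over all pairs
min_concurrent_spacing <- function(attractors, ticks, patch_edge_km) {
  a <- attractors
  a$until <- ifelse(is.na(a$collapsed_tick), ticks + 1L, a$collapsed_tick)
  best <- Inf
  n <- nrow(a)
  if (n < 2) return(best)
  for (i in seq_len(n - 1)) {
    for (j in seq.int(i + 1, n)) {
      if (max(a$founded_tick[i], a$founded_tick[j]) <
          min(a$until[i], a$until[j])) {
        d <- sqrt((a$x[i] - a$x[j])^2 + (a$y[i] - a$y[j])^2) * patch_edge_km
        best <- min(best, d)
      }
    }
  }
  best
}
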