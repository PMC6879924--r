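## Database orchestration: simulate the baseline subjects and the offset
## grid, extract indexes, apply the plausibility filter, and export the
## index table (the database manifest) as plain CSV.

#' Generate a virtual-subject pulse wave database
#'
#' Simulates the baseline subject at each age followed by the full
#' 3^k offset grid of the varied factors, analyses every subject and
#' flags BP plausibility. The returned index table has one row per
#' subject (age, offsets, prescribed values, derived indexes, plausibility
#' flag) and is the database manifest; individual pulse wave sets can be
#' retained via `keep_waves`.
#'
#' The full six-factor grid is 729 subjects per age; small studies
#' restrict `factors` (e.g. a single factor gives 3 subjects per age).
#'
#' @param ages Ages, years.
#' @param factors Varied factors, default all six.
#' @param base_network Base network, default the reduced fixture.
#' @param options [solver_options()].
#' @param keep_waves Keep the simulated `pw_pulse_set`s (memory-hungry).
#' @param progress Print one line per subject.
#' @return Object of class `pw_database`: list with `index` (tibble),
#'   `waves` (list or NULL), `ages`, `factors`.
#' @export
run_database <- function(ages, factors = varied_factors(),
                         base_network = default_base_network(),
                         options = solver_options(),
                         keep_waves = FALSE, progress = FALSE) {
  grid <- generate_grid(ages, factors)
  offs <- paste0("off_", factors)
  rows <- vector("list", nrow(grid))
  waves <- if (keep_waves) vector("list", nrow(grid)) else NULL
  for (i in seq_len(nrow(grid))) {
    g <- grid[i, ]
    off <- setNames(as.numeric(g[offs]), sub("^off_", "", offs))
    off <- off[off != 0]
    status <- "ok"
    row <- tryCatch({
      pws <- simulate_virtual_subject(g$age, if (length(off)) off else NULL,
                                      base_network = base_network,
                                      options = options)
      if (keep_waves) waves[[i]] <<- pws
      analyze_subject(pws)
    }, error = function(e) {
      status <<- conditionMessage(e)
      NULL
    })
    if (is.null(row)) {
      row <- tibble(age = g$age, plausible = NA)
    }
    row$subject <- g$subject
    row$status <- status
    rows[[i]] <- row
    if (progress) {
      cat(sprintf("age %g subject %d/%d: %s\n", g$age, g$subject,
                  nrow(grid[grid$age == g$age, ]), status))
    }
  }
  index <- bind_rows(rows)
  structure(list(index = index, waves = waves, ages = ages,
                 factors = factors),
            class = "pw_database")
}

#' @export
print.pw_database <- function(x, ...) {
  n <- nrow(x$index)
  npl <- sum(x$index$plausible, na.rm = TRUE)
  cat(sprintf("<pw_database> %d subjects (%d plausible) at ages %s; varied: %s\n",
              n, npl, paste(x$ages, collapse = ", "),
              paste(x$factors, collapse = ", ")))
  invisible(x)
}

#' @export
glance.pw_database <- function(x, ...) {
  tibble(n_subjects = nrow(x$index),
         n_plausible = sum(x$index$plausible, na.rm = TRUE),
         n_ages = length(x$ages),
         n_factors = length(x$factors))
}

#' Export a database index (and optional per-site waves) to CSV
#'
#' @param db A `pw_database`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_database <- function(db, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  utils::write.csv(db$index, file.path(dir, "index.csv"), row.names = FALSE)
  if (!is.null(db$waves)) {
    for (i in seq_along(db$waves)) {
      w <- db$waves[[i]]
      if (is.null(w)) next
      utils::write.csv(as.data.frame(w),
                       file.path(dir, sprintf("subject_%04d_waves.csv", i)),
                       row.names = FALSE)
    }
  }
  invisible(dir)
}
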