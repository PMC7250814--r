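# JSON model configs and CSV tables. Configs are plain JSON with keys
# m, n, A, B, C, D (destination-major nested lists) and an optional
# demography block; all numbers are written at full double precision so a
# write/read round trip is lossless.

tensor_to_nested <- function(Tn) {
  d <- dim(Tn)
  lapply(seq_len(d[1L]), function(k) {
    lapply(seq_len(d[2L]), function(i) as.numeric(Tn[k, i, ]))
  })
}

nested_to_tensor <- function(lst, k, s, what) {
  Tn <- array(NA_real_, dim = c(k, k, s))
  if (length(lst) != k) {
    stop(sprintf("config key '%s': expected %d destination entries, got %d",
                 what, k, length(lst)), call. = FALSE)
  }
  for (dk in seq_len(k)) {
    row <- lst[[dk]]
    if (length(row) != k) {
      stop(sprintf("config key '%s[%d]': expected %d source entries, got %d",
                   what, dk, k, length(row)), call. = FALSE)
    }
    for (i in seq_len(k)) {
      v <- as.numeric(unlist(row[[i]]))
      if (length(v) != s) {
        stop(sprintf("config key '%s[%d][%d]': expected %d mediator entries, got %d",
                     what, dk, i, s, length(v)), call. = FALSE)
      }
      Tn[dk, i, ] <- v
    }
  }
  Tn
}

config_matrix <- function(lst, k, what) {
  M <- do.call(rbind, lapply(lst, function(r) as.numeric(unlist(r))))
  if (is.null(M) || nrow(M) != k || ncol(M) != k) {
    stop(sprintf("config key '%s': expected a %d x %d matrix", what, k, k),
         call. = FALSE)
  }
  M
}

#' Write a model configuration to JSON
#'
#' @param model a [transition_model()].
#' @param path output file path.
#' @param rates optional [demography_rates()] stored under `demography`.
#' @return `path`, invisibly.
#' @export
write_model_config <- function(model, path, rates = NULL) {
  cfg <- list(
    m = model$m, n = model$n,
    A = lapply(seq_len(model$m), function(k) as.numeric(model$A[k, ])),
    B = tensor_to_nested(model$B),
    C = tensor_to_nested(model$C),
    D = lapply(seq_len(model$n), function(k) as.numeric(model$D[k, ])),
    relaxed = model$relaxed
  )
  if (!is.null(model$name)) cfg$name <- model$name
  if (!is.null(rates)) {
    cfg$demography <- list(
      beta = lapply(seq_len(rates$m), function(i) as.numeric(rates$beta[i, ])),
      lam = rates$lam, mu = rates$mu,
      gamma = lapply(seq_len(rates$m), function(i) as.numeric(rates$gamma[i, ])),
      delta = rates$delta,
      prey_offspring = rates$prey_offspring,
      pred_offspring = rates$pred_offspring
    )
  }
  # I(17) = 17 *significant* digits, enough to round-trip IEEE doubles
  jsonlite::write_json(cfg, path, digits = I(17), auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(path)
}

#' Read a model configuration from JSON
#'
#' Parses and validates the documented schema (`m`, `n`, `A`, `B`, `C`,
#' `D`, optional `demography`, `relaxed`, `name`), distinguishing schema
#' errors (wrong shapes, missing keys - reported with the offending key and
#' index) from consistency violations (valid shapes but broken column
#' sums - reported via [validate_consistency()]).
#'
#' @param path JSON file path.
#' @param check if `TRUE` (default) the model must pass
#'   [validate_consistency()].
#' @return List with `model` (a [transition_model()]) and `rates` (a
#'   [demography_rates()] or `NULL`).
#' @export
read_model_config <- function(path, check = TRUE) {
  if (!file.exists(path)) stop("config file not found: ", path,
                               call. = FALSE)
  cfg <- jsonlite::read_json(path, simplifyVector = FALSE)
  for (key in c("m", "n", "A", "B", "C", "D")) {
    if (is.null(cfg[[key]])) {
      stop(sprintf("config key '%s' is missing", key), call. = FALSE)
    }
  }
  m <- as.integer(cfg$m)
  n <- as.integer(cfg$n)
  model <- transition_model(
    A = config_matrix(cfg$A, m, "A"),
    D = config_matrix(cfg$D, n, "D"),
    B = nested_to_tensor(cfg$B, m, n, "B"),
    C = nested_to_tensor(cfg$C, n, m, "C"),
    relaxed = isTRUE(cfg$relaxed),
    name = if (!is.null(cfg$name)) as.character(cfg$name)
  )
  if (check) {
    rep <- validate_consistency(model)
    if (nrow(rep) > 0L) {
      stop(sprintf("config '%s' parsed but is inconsistent: %s [%s column %s]",
                   path, rep$message[1L], rep$component[1L],
                   as.character(rep$column[1L])), call. = FALSE)
    }
  }
  rates <- NULL
  if (!is.null(cfg$demography)) {
    dgr <- cfg$demography
    rates <- demography_rates(
      m = m, n = n,
      beta = if (!is.null(dgr$beta)) config_rect(dgr$beta, m, n, "beta"),
      lam = if (!is.null(dgr$lam)) as.numeric(unlist(dgr$lam)) else 0,
      mu = if (!is.null(dgr$mu)) as.numeric(unlist(dgr$mu)) else 0,
      gamma = if (!is.null(dgr$gamma)) config_rect(dgr$gamma, m, n, "gamma"),
      delta = if (!is.null(dgr$delta)) as.numeric(unlist(dgr$delta)) else 0,
      prey_offspring = if (!is.null(dgr$prey_offspring))
        as.numeric(unlist(dgr$prey_offspring)),
      pred_offspring = if (!is.null(dgr$pred_offspring))
        as.numeric(unlist(dgr$pred_offspring))
    )
  }
  list(model = model, rates = rates)
}

config_rect <- function(lst, nr, nc, what) {
  M <- do.call(rbind, lapply(lst, function(r) as.numeric(unlist(r))))
  if (is.null(M) || nrow(M) != nr || ncol(M) != nc) {
    stop(sprintf("config key 'demography$%s': expected a %d x %d matrix",
                 what, nr, nc), call. = FALSE)
  }
  M
}

fmt17 <- function(x) {
  ifelse(is.na(x), "NA", sprintf("%.17g", x))
}

#' Write a response surface as CSV
#'
#' One row per grid cell in X-major order (X varies slowest), columns
#' `X,Y,f,g,gamma,delta,net,converged`, numbers at 17 significant digits so
#' re-reading reproduces the surface exactly and re-running produces a
#' byte-identical file.
#'
#' @param surface a [response_surface()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_response_table <- function(surface, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines("X,Y,f,g,gamma,delta,net,converged", con)
  for (ix in seq_along(surface$X_grid)) {
    for (iy in seq_along(surface$Y_grid)) {
      writeLines(paste(
        fmt17(surface$X_grid[ix]), fmt17(surface$Y_grid[iy]),
        fmt17(surface$f[ix, iy]), fmt17(surface$g[ix, iy]),
        fmt17(surface$gamma[ix, iy]), fmt17(surface$delta[ix, iy]),
        fmt17(surface$net[ix, iy]),
        if (surface$converged[ix, iy]) "TRUE" else "FALSE",
        sep = ","), con)
    }
  }
  invisible(path)
}

#' Read a response-surface CSV back into matrices
#'
#' @param path CSV written by [write_response_table()].
#' @return An object of class `response_surface`.
#' @export
read_response_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  X_grid <- sort(unique(df$X))
  Y_grid <- sort(unique(df$Y))
  mk <- function(col) {
    matrix(as.numeric(col), length(X_grid), length(Y_grid), byrow = TRUE,
           dimnames = list(signif(X_grid, 8), signif(Y_grid, 8)))
  }
  out <- list(X_grid = X_grid, Y_grid = Y_grid, f = mk(df$f), g = mk(df$g),
              gamma = mk(df$gamma), delta = mk(df$delta), net = mk(df$net),
              converged = mk(df$converged) > 0)
  class(out) <- "response_surface"
  out
}

#' Write a trajectory as CSV
#'
#' @param traj a `trajectory`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(traj, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(paste(c("time", traj$columns), collapse = ","), con)
  for (i in seq_along(traj$times)) {
    writeLines(paste(fmt17(c(traj$times[i], traj$states[i, ])),
                     collapse = ","), con)
  }
  invisible(path)
}
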