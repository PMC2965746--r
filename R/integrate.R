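#' Integrate a chemostat model over time
#'
#' Runs a model right-hand side through deSolve's variable-step solvers and
#' returns a `crispr_trajectory`: states at the reporting grid plus an event
#' log. For models with a phage population, the loss rule is applied at
#' solver-reported steps: the first time the free-phage density falls below
#' `env$phage_extinction_threshold` (while still positive), the phage state is
#' set to exactly zero, a `"phage_extinct"` event is logged, and integration
#' resumes from that state; with `P = 0` every phage term vanishes, so the
#' phage stay at zero. Reported densities are floored at zero; the solver
#' itself works on raw densities (no log transform), which keeps the
#' extinction-event semantics exact.
#'
#' @param rhs A function `(state, params, env) -> named derivative vector`,
#'   e.g. [phage_rhs()] or [plasmid_rhs()].
#' @param initial Named nonnegative numeric state vector; last element must
#'   be the resource `R`.
#' @param params Parameter object passed through to `rhs`.
#' @param env A [chemostat_env()].
#' @param t_end End time (hr), > 0.
#' @param report_dt Reporting interval (hr).
#' @param rtol,atol Relative and absolute solver tolerances.
#' @param method deSolve method; `"lsoda"` (stiff-capable, default) or any
#'   other method accepted by [deSolve::ode()], e.g. `"ode45"`.
#' @param phage_var Name of the phage state variable (`"P"` for the phage
#'   model), or `NULL` when the model has no phage.
#' @param model Label stored on the trajectory (`"phage"`, `"plasmid"`, ...).
#'
#' @return An object of class `crispr_trajectory`: a list with elements
#'   `model`, `time` (strictly increasing reporting times), `state` (matrix,
#'   one row per time, columns in roster order ending with `R`), `events`
#'   (data frame of `time`, `event`), `params`, `env`, `solver`.
#' @export
integrate_model <- function(rhs, initial, params, env, t_end,
                            report_dt = 0.5, rtol = 1e-8, atol = 1e-10,
                            method = "lsoda", phage_var = NULL,
                            model = "custom") {
  stopifnot(inherits(env, "chemostat_env"))
  if (!is.numeric(t_end) || length(t_end) != 1L || t_end <= 0)
    stop("'t_end' must be a positive time in hours")
  y <- unlist(initial)
  if (is.null(names(y)) || any(!nzchar(names(y))))
    stop("'initial' must be a fully named state vector")
  if (any(!is.finite(y)) || any(y < 0))
    stop("'initial' densities must be finite and nonnegative")

  events <- data.frame(time = numeric(), event = character())
  thr <- env$phage_extinction_threshold
  if (!is.null(phage_var) && y[[phage_var]] > 0 && y[[phage_var]] < thr) {
    y[[phage_var]] <- 0
    events <- rbind(events, data.frame(time = 0, event = "phage_extinct"))
  }

  func <- function(t, state, parms) {
    d <- rhs(state, params, env)
    list(unname(d[names(state)]))
  }

  segments <- list()
  t0 <- 0
  repeat {
    times <- seq(t0, t_end, by = report_dt)
    if (times[length(times)] < t_end) times <- c(times, t_end)
    out <- try(suppressWarnings(
      deSolve::ode(y = y, times = times, func = func, parms = NULL,
                   method = method, rtol = rtol, atol = atol,
                   maxsteps = 5e5)),
      silent = TRUE)
    bad <- inherits(out, "try-error") || any(!is.finite(out))
    if (!bad && nrow(out) < length(times)) bad <- TRUE
    if (bad) {
      last_ok <- if (inherits(out, "try-error")) c(time = t0, y) else {
        ok <- apply(is.finite(out), 1, all)
        out[max(which(ok)), ]
      }
      cond <- structure(
        class = c("crisprdyn_integration_error", "error", "condition"),
        list(message = sprintf("ODE solver failed near t = %.3f hr", last_ok[["time"]]),
             call = sys.call(-1), last_state = last_ok))
      stop(cond)
    }
    sm <- pmax(unclass(out)[, -1, drop = FALSE], 0)
    tt <- out[, 1]

    if (!is.null(phage_var)) {
      pcol <- sm[, phage_var]
      hit <- which(pcol > 0 & pcol < thr)
      if (length(hit) > 0) {
        i <- hit[1]
        sm <- sm[seq_len(i), , drop = FALSE]
        tt <- tt[seq_len(i)]
        sm[i, phage_var] <- 0
        events <- rbind(events,
                        data.frame(time = tt[i], event = "phage_extinct"))
        segments[[length(segments) + 1L]] <- list(time = tt, state = sm)
        if (tt[i] >= t_end) break
        y <- sm[i, ]
        t0 <- tt[i]
        next
      }
    }
    segments[[length(segments) + 1L]] <- list(time = tt, state = sm)
    break
  }

  time  <- do.call(c, lapply(segments, `[[`, "time"))
  state <- do.call(rbind, lapply(segments, `[[`, "state"))
  keep <- !duplicated(time)  # restart rows repeat the event time; keep first (P already zeroed)
  time <- time[keep]
  state <- state[keep, , drop = FALSE]
  rownames(state) <- NULL

  structure(
    list(model = model, time = time, state = state, events = events,
         params = params, env = env,
         solver = list(method = method, rtol = rtol, atol = atol,
                       report_dt = report_dt, t_end = t_end)),
    class = "crispr_trajectory")
}

#' Simulate the lytic-phage model
#'
#' @param params A [phage_params()].
#' @param env A [chemostat_env()].
#' @param initial A [phage_state()] vector.
#' @param t_end End time (hr).
#' @param ... Passed to [integrate_model()] (`report_dt`, `rtol`, `atol`,
#'   `method`).
#' @return A `crispr_trajectory`.
#' @examples
#' env <- chemostat_env()
#' tr <- simulate_phage(phage_params(m = 0, mu = 0), env,
#'                      phage_state(N = 1e6, P = 1e4, R = env$A), t_end = 20)
#' tail(as.data.frame(tr), 2)
#' @export
simulate_phage <- function(params, env, initial, t_end, ...) {
  stopifnot(inherits(params, "phage_params"))
  initial <- phage_state(initial[["N"]], initial[["N_R"]], initial[["C"]],
                         initial[["C_R"]], initial[["P"]], initial[["R"]])
  integrate_model(phage_rhs, initial, params, env, t_end,
                  phage_var = "P", model = "phage", ...)
}

#' Simulate the conjugative-plasmid model
#'
#' @param params A [plasmid_params()].
#' @param env A [chemostat_env()].
#' @param initial A [plasmid_state()] vector.
#' @param t_end End time (hr).
#' @param ... Passed to [integrate_model()].
#' @return A `crispr_trajectory`.
#' @export
simulate_plasmid <- function(params, env, initial, t_end, ...) {
  stopifnot(inherits(params, "plasmid_params"))
  initial <- plasmid_state(initial[["N"]], initial[["N_P"]], initial[["C"]],
                           initial[["C_P"]], initial[["C_X"]], initial[["R"]])
  integrate_model(plasmid_rhs, initial, params, env, t_end,
                  phage_var = NULL, model = "plasmid", ...)
}

#' @export
print.crispr_trajectory <- function(x, ...) {
  cat(sprintf("<crispr_trajectory> %s model, %d time points over [0, %g] hr\n",
              x$model, length(x$time), max(x$time)))
  fin <- x$state[nrow(x$state), ]
  cat("  final state:", paste(sprintf("%s=%.4g", names(fin), fin), collapse = ", "), "\n")
  if (nrow(x$events) > 0) {
    cat("  events:", paste(sprintf("%s@%.2g hr", x$events$event, x$events$time),
                           collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
as.data.frame.crispr_trajectory <- function(x, ...) {
  pops <- setdiff(colnames(x$state), "R")
  df <- data.frame(t = x$time,
                   R = x$state[, "R"],
                   x$state[, pops, drop = FALSE],
                   check.names = FALSE)
  rownames(df) <- NULL
  df
}

#' Write a trajectory to a delimited text file
#'
#' One row per reporting time; columns `t`, `R`, then population densities in
#' roster order, then one 0/1 flag column per event type (1 from the event
#' time onward). Header row always written.
#'
#' @param traj A `crispr_trajectory`.
#' @param file Path of the CSV file to write.
#' @return `file`, invisibly.
#' @export
write_trajectory <- function(traj, file) {
  stopifnot(inherits(traj, "crispr_trajectory"))
  df <- as.data.frame(traj)
  for (ev in unique(traj$events$event)) {
    t_ev <- min(traj$events$time[traj$events$event == ev])
    df[[ev]] <- as.integer(df$t >= t_ev)
  }
  utils::write.csv(df, file, row.names = FALSE, quote = FALSE)
  invisible(file)
}
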