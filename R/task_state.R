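#' Dual-feeder task states
#'
#' The automated dual-feeder task has four states. In `DEFAULT` only the
#' low-quality reward is accessible; an unsuccessful (different-class) dyadic
#' association triggers a `LOCKOUT` during which neither reward is
#' accessible; a successful (same-class) association outside a lockout opens
#' both rewards (`SUCCESS`); a successful association during a lockout
#' overrides it and opens the high-quality reward only (`SUCCESS_OVERRIDE`).
#'
#' @format Character vector of the four state names.
#' @export
TASK_STATES <- c("DEFAULT", "LOCKOUT", "SUCCESS", "SUCCESS_OVERRIDE")

#' Create a dual-feeder task state
#'
#' @param state One of [TASK_STATES].
#' @param lockout_remaining Seconds of lockout still pending (counts down in
#'   `LOCKOUT` and, while a lockout is overridden, in `SUCCESS_OVERRIDE`).
#' @param success_elapsed Seconds since the onset of the current successful
#'   association (used to enforce the minimum access window).
#' @param success_remaining Seconds of reward access still owed after a
#'   successful dyad departed before the minimum access window elapsed.
#' @return An object of class `task_state`.
#' @export
task_state <- function(state = "DEFAULT", lockout_remaining = 0,
                       success_elapsed = 0, success_remaining = 0) {
  state <- match.arg(state, TASK_STATES)
  stopifnot(lockout_remaining >= 0, success_elapsed >= 0,
            success_remaining >= 0)
  if (lockout_remaining > 0 && !state %in% c("LOCKOUT", "SUCCESS_OVERRIDE"))
    stop("lockout_remaining > 0 is only valid in LOCKOUT or SUCCESS_OVERRIDE")
  structure(list(state = state, lockout_remaining = lockout_remaining,
                 success_elapsed = success_elapsed,
                 success_remaining = success_remaining),
            class = "task_state")
}

#' Reward accessibility by task state
#'
#' Accessibility is a function of the state alone: `DEFAULT` opens only the
#' low-quality reward, `LOCKOUT` neither, `SUCCESS` both, and
#' `SUCCESS_OVERRIDE` the high-quality reward only.
#'
#' @param state A `task_state` or a state name.
#' @return Named logical vector `c(low = , high = )`.
#' @export
reward_access <- function(state) {
  if (inherits(state, "task_state")) state <- state$state
  state <- match.arg(state, TASK_STATES)
  switch(state,
         DEFAULT          = c(low = TRUE,  high = FALSE),
         LOCKOUT          = c(low = FALSE, high = FALSE),
         SUCCESS          = c(low = TRUE,  high = TRUE),
         SUCCESS_OVERRIDE = c(low = FALSE, high = TRUE))
}

# Advance timers by dt under the current occupancy-free dynamics:
# lockout expiry (LOCKOUT -> DEFAULT; SUCCESS_OVERRIDE -> SUCCESS when the
# lockout runs out during an ongoing success) and expiry of the minimum
# access window owed to a departed successful dyad.
advance_task_state <- function(ts, dt) {
  if (dt <= 0) return(ts)
  st <- ts$state
  if (st == "LOCKOUT") {
    rem <- ts$lockout_remaining - dt
    if (rem <= 0) return(task_state("DEFAULT"))
    return(task_state("LOCKOUT", lockout_remaining = rem))
  }
  if (st == "SUCCESS") {
    if (ts$success_remaining > 0) {
      # dyad already departed; reward window still open
      rem <- ts$success_remaining - dt
      if (rem <= 0) return(task_state("DEFAULT"))
      return(task_state("SUCCESS", success_elapsed = ts$success_elapsed + dt,
                        success_remaining = rem))
    }
    return(task_state("SUCCESS", success_elapsed = ts$success_elapsed + dt))
  }
  if (st == "SUCCESS_OVERRIDE") {
    lock <- ts$lockout_remaining - dt
    if (ts$success_remaining > 0) {
      srem <- ts$success_remaining - dt
      if (srem <= 0) {
        # owed window closed: fall back to whatever lockout is left
        if (lock <= 0) return(task_state("DEFAULT"))
        return(task_state("LOCKOUT", lockout_remaining = lock))
      }
      if (lock <= 0)
        return(task_state("SUCCESS", success_elapsed = ts$success_elapsed + dt,
                          success_remaining = srem))
      return(task_state("SUCCESS_OVERRIDE", lockout_remaining = lock,
                        success_elapsed = ts$success_elapsed + dt,
                        success_remaining = srem))
    }
    if (lock <= 0)  # lockout expired during the ongoing success
      return(task_state("SUCCESS", success_elapsed = ts$success_elapsed + dt))
    return(task_state("SUCCESS_OVERRIDE", lockout_remaining = lock,
                      success_elapsed = ts$success_elapsed + dt))
  }
  ts  # DEFAULT is absorbing under pure time flow
}

#' Step the dual-feeder task state machine
#'
#' Advances the state by `dt` seconds (handling lockout expiry and the
#' minimum-access window), then applies the occupancy signal. A forming
#' dyad with matching treatment classes triggers a success (or a lockout
#' override); a mismatched dyad triggers (or restarts) a lockout, including
#' the direct success-to-lockout transition when an unsuccessful association
#' immediately follows a successful one. When a dyad dissolves (`occupancy`
#' `"solo"` or `"empty"`), a success whose minimum access window has not yet
#' elapsed keeps its reward open for the remainder of the window.
#'
#' @param ts A [task_state()].
#' @param occupancy One of `"empty"`, `"solo"`, `"dyad"`.
#' @param class_match For `occupancy = "dyad"`, logical: do the two
#'   occupants share a treatment class?
#' @param dt Seconds elapsed since the previous step (default 0).
#' @param lockout_duration Lockout length in seconds (default 120).
#' @param min_success_access Minimum seconds of high-quality access from the
#'   onset of a successful association (default 15).
#' @return A list with elements `state` (the new `task_state`) and `access`
#'   (the [reward_access()] vector of the new state).
#' @export
step_task_state <- function(ts, occupancy, class_match = NA, dt = 0,
                            lockout_duration = 120, min_success_access = 15) {
  if (!inherits(ts, "task_state")) stop("ts must be a task_state")
  occupancy <- match.arg(occupancy, c("empty", "solo", "dyad"))
  if (dt < 0) stop("dt must be non-negative")
  ts <- advance_task_state(ts, dt)
  st <- ts$state

  if (occupancy == "dyad") {
    if (is.na(class_match)) stop("class_match required when occupancy is 'dyad'")
    if (class_match) {
      new <- switch(st,
        DEFAULT = task_state("SUCCESS"),
        LOCKOUT = task_state("SUCCESS_OVERRIDE",
                             lockout_remaining = ts$lockout_remaining),
        SUCCESS = task_state("SUCCESS"),
        SUCCESS_OVERRIDE = task_state("SUCCESS_OVERRIDE",
                                      lockout_remaining = ts$lockout_remaining))
    } else {
      # any unsuccessful dyad (re)starts a full lockout, from any state
      new <- task_state("LOCKOUT", lockout_remaining = lockout_duration)
    }
  } else {  # solo or empty: a dyad (if any) has dissolved
    new <- switch(st,
      DEFAULT = ts,
      LOCKOUT = ts,
      SUCCESS = {
        if (ts$success_remaining > 0) ts  # already in the owed window
        else if (ts$success_elapsed < min_success_access)
          task_state("SUCCESS", success_elapsed = ts$success_elapsed,
                     success_remaining = min_success_access - ts$success_elapsed)
        else task_state("DEFAULT")
      },
      SUCCESS_OVERRIDE = {
        if (ts$success_remaining > 0) ts
        else if (ts$success_elapsed < min_success_access)
          task_state("SUCCESS_OVERRIDE",
                     lockout_remaining = ts$lockout_remaining,
                     success_elapsed = ts$success_elapsed,
                     success_remaining = min_success_access - ts$success_elapsed)
        else task_state("LOCKOUT", lockout_remaining = ts$lockout_remaining)
      })
  }
  list(state = new, access = reward_access(new))
}

#' @export
print.task_state <- function(x, ...) {
  cat("<task_state>", x$state)
  if (x$lockout_remaining > 0)
    cat(sprintf(" [lockout %gs remaining]", x$lockout_remaining))
  if (x$success_remaining > 0)
    cat(sprintf(" [access window %gs remaining]", x$success_remaining))
  cat("\n")
  invisible(x)
}
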