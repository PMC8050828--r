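#' States and cues of the responsive cargo device
#'
#' The reconfigurable device holds a fluorescent cargo in one of three
#' anchoring configurations: State1 (cargo on the tocopherol `sT` module,
#' Ld-preferring), State2 (cargo bridging the `sT` and `dC` modules), and
#' State3 (cargo on the double-cholesterol `dC` module, Lo-preferring).
#' Fuel and antifuel strands drive toehold-mediated strand displacement
#' between the configurations:
#' `Fuel1`: 1 -> 2, `Antifuel2`: 2 -> 3, `Fuel2`: 3 -> 2, `Antifuel1`:
#' 2 -> 1.  Any other (state, cue) pair is a no-op.
#'
#' @name cargo_state_machine
#' @keywords internal
NULL

cargo_states <- c("State1", "State2", "State3")
cargo_cues <- c("Fuel1", "Antifuel1", "Fuel2", "Antifuel2")
# cues whose transitions run the reverse path (back toward State1)
reverse_cues <- c("Antifuel1", "Fuel2")

cargo_transitions <- data.frame(
  from = c("State1", "State2", "State3", "State2"),
  cue  = c("Fuel1", "Antifuel2", "Fuel2", "Antifuel1"),
  to   = c("State2", "State3", "State2", "State1"),
  stringsAsFactors = FALSE
)

#' Apply a fuel/antifuel cue to a cargo state
#'
#' @param state current state, one of `"State1"`, `"State2"`, `"State3"`.
#' @param cue one of `"Fuel1"`, `"Antifuel1"`, `"Fuel2"`, `"Antifuel2"`.
#' @return the next state; unlisted (state, cue) pairs return the input
#'   state unchanged with a warning.
#' @examples
#' apply_cue("State1", "Fuel1")   # "State2"
#' @export
apply_cue <- function(state, cue) {
  if (!state %in% cargo_states) stop("unknown state: ", state, call. = FALSE)
  if (!cue %in% cargo_cues) stop("unknown cue: ", cue, call. = FALSE)
  hit <- cargo_transitions$from == state & cargo_transitions$cue == cue
  if (!any(hit)) {
    warning("cue ", cue, " has no effect in ", state, " (no-op)", call. = FALSE)
    return(state)
  }
  cargo_transitions$to[hit]
}

#' Equilibrium fractional intensity of a cargo state
#'
#' Maps each anchoring configuration to its equilibrium f: State1 uses the
#' sT-only baseline, State3 the dC-only baseline, and State2 either the
#' additive sT+dC prediction (sum of the library contributions) or a
#' supplied measured sT+dC free energy.  An optional hysteresis offset is
#' added to equilibria reached along the reverse path, modelling the
#' incomplete reversibility seen experimentally (f values slightly higher
#' on return than at first).
#'
#' @param state `"State1"`, `"State2"` or `"State3"`.
#' @param anchor_library data.frame with columns `tag`, `dG` providing `sT`
#'   and `dC` entries (see [default_anchor_library()]).
#' @param state2_mode `"additive"` (sum sT + dC from the library) or
#'   `"measured"` (use `measured_sT_dC`).
#' @param measured_sT_dC measured sT+dC free energy, kBT (used when
#'   `state2_mode = "measured"`).
#' @param hysteresis additive offset on reverse-path equilibria (default 0).
#' @param reverse whether this equilibrium is being approached along the
#'   reverse path.
#' @return equilibrium fractional intensity in (0, 1).
#' @export
state_equilibrium_f <- function(state,
                                anchor_library = default_anchor_library(),
                                state2_mode = c("additive", "measured"),
                                measured_sT_dC = 1.0,
                                hysteresis = 0, reverse = FALSE) {
  state2_mode <- match.arg(state2_mode)
  if (!state %in% cargo_states) stop("unknown state: ", state, call. = FALSE)
  dG <- switch(state,
    State1 = anchor_dG(anchor_library, "sT"),
    State3 = anchor_dG(anchor_library, "dC"),
    State2 = if (state2_mode == "additive") {
      anchor_dG(anchor_library, "sT") + anchor_dG(anchor_library, "dC")
    } else {
      measured_sT_dC
    })
  f <- dG_to_fraction(dG)
  if (reverse) f <- min(max(f + hysteresis, 0), 1)
  f
}

#' Exponential relaxation trace of the fractional intensity
#'
#' Single-exponential approach of f toward its new equilibrium,
#' \deqn{f(t) = f_{eq} + (f_0 - f_{eq}) e^{-t/\tau},}
#' the redistribution kinetics observed after fuel addition (equilibration
#' on the ~5 min scale, limited by fuel diffusion through the sample).
#'
#' @param f0 initial fractional intensity.
#' @param f_eq equilibrium fractional intensity.
#' @param tau relaxation time constant, minutes (> 0).
#' @param times non-decreasing vector of times, minutes.
#' @return data.frame of class `relaxation_trace`: `time_min`, `f`.
#' @export
relax_trace <- function(f0, f_eq, tau, times) {
  if (!is.numeric(tau) || tau <= 0) stop("`tau` must be > 0", call. = FALSE)
  if (is.unsorted(times)) stop("`times` must be non-decreasing", call. = FALSE)
  if (f0 < 0 || f0 > 1 || f_eq < 0 || f_eq > 1) {
    stop("fractions must lie in [0, 1]", call. = FALSE)
  }
  f <- f_eq + (f0 - f_eq) * exp(-times / tau)
  structure(data.frame(time_min = times, f = f),
            class = c("relaxation_trace", "data.frame"))
}

#' Simulate a full fuel/antifuel protocol
#'
#' Runs the cargo state machine through a timed cue protocol: the state (and
#' hence the attractor f) changes instantaneously at each cue time, while f
#' itself relaxes continuously with time constant `tau` — the trace is
#' continuous at cue times; only its target changes.
#'
#' @param protocol data.frame with columns `time_min` (strictly increasing,
#'   > 0) and `cue`; zero rows give a flat trace at the initial equilibrium.
#' @param anchor_library,state2_mode,measured_sT_dC,hysteresis passed to
#'   [state_equilibrium_f()].
#' @param tau relaxation time constant, minutes.
#' @param initial_state starting configuration (default `"State1"`).
#' @param dt sampling interval, minutes.
#' @param t_end trace end time; default last cue + 6 tau (or 6 tau with no
#'   cues).
#' @return data.frame of class `protocol_trace`: `time_min`, `state`, `f`.
#' @export
simulate_protocol <- function(protocol,
                              anchor_library = default_anchor_library(),
                              state2_mode = c("additive", "measured"),
                              measured_sT_dC = 1.0,
                              hysteresis = 0,
                              tau = 5, initial_state = "State1",
                              dt = 0.1, t_end = NULL) {
  state2_mode <- match.arg(state2_mode)
  if (!is.data.frame(protocol)) {
    stop("`protocol` must be a data.frame with columns time_min, cue",
         call. = FALSE)
  }
  if (nrow(protocol) > 0) {
    stopifnot(all(c("time_min", "cue") %in% names(protocol)))
    if (any(diff(protocol$time_min) <= 0) || any(protocol$time_min <= 0)) {
      stop("cue times must be strictly increasing and > 0", call. = FALSE)
    }
  }
  if (is.null(t_end)) {
    t_end <- if (nrow(protocol)) max(protocol$time_min) + 6 * tau else 6 * tau
  }
  grid <- sort(unique(c(seq(0, t_end, by = dt), protocol$time_min, t_end)))

  eq_of <- function(state, reverse) {
    state_equilibrium_f(state, anchor_library, state2_mode, measured_sT_dC,
                        hysteresis, reverse)
  }
  seg_start <- 0
  state <- initial_state
  f_start <- eq_of(state, reverse = FALSE)
  f_eq <- f_start
  cue_i <- 1L
  out_t <- numeric(0); out_f <- numeric(0); out_s <- character(0)
  for (t in grid) {
    while (cue_i <= nrow(protocol) && t >= protocol$time_min[cue_i]) {
      t_cue <- protocol$time_min[cue_i]
      f_at_cue <- f_eq + (f_start - f_eq) * exp(-(t_cue - seg_start) / tau)
      cue <- protocol$cue[cue_i]
      state <- suppressWarnings(apply_cue(state, cue))
      f_start <- f_at_cue
      seg_start <- t_cue
      f_eq <- eq_of(state, reverse = cue %in% reverse_cues)
      cue_i <- cue_i + 1L
    }
    out_t <- c(out_t, t)
    out_f <- c(out_f, f_eq + (f_start - f_eq) * exp(-(t - seg_start) / tau))
    out_s <- c(out_s, state)
  }
  structure(data.frame(time_min = out_t, state = out_s, f = out_f,
                       stringsAsFactors = FALSE),
            class = c("protocol_trace", "data.frame"))
}
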