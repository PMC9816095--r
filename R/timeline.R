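#' Injection timeline of the lithium-pilocarpine protocol
#'
#' The experiment clock is anchored at the scopolamine injection (t = 0 s).
#' Defaults follow the standard protocol: scopolamine at T = 0 min, first
#' pilocarpine dose at T = 30, second pilocarpine dose at T = 60, diazepam at
#' T = 120, with the magnet (or sham replica) applied from scopolamine until
#' the second pilocarpine dose.
#'
#' @param scopolamine_t scopolamine injection time (s).
#' @param pilocarpine1_t first pilocarpine dose (s).
#' @param pilocarpine2_t second pilocarpine dose (s).
#' @param diazepam_t diazepam injection (s).
#' @param magnet_on numeric length-2, interval (s) during which the magnet or
#'   sham replica sits on the skull.
#' @return an object of class `ecosyn_timeline`.
#' @examples
#' timeline()                  # the default 0/30/60/120-min schedule
#' timeline(0, 300, 600, 1200) # a compressed schedule for quick simulations
#' @export
timeline <- function(scopolamine_t = 0, pilocarpine1_t = 1800,
                     pilocarpine2_t = 3600, diazepam_t = 7200,
                     magnet_on = c(scopolamine_t, pilocarpine2_t)) {
  for (nm in c("scopolamine_t", "pilocarpine1_t", "pilocarpine2_t", "diazepam_t"))
    stopifnot_scalar_number(get(nm), nm)
  if (!(scopolamine_t < pilocarpine1_t && pilocarpine1_t < pilocarpine2_t &&
        pilocarpine2_t < diazepam_t))
    abort_validation("timeline must satisfy scopolamine < pilocarpine1 < pilocarpine2 < diazepam")
  if (length(magnet_on) != 2L || magnet_on[2] < magnet_on[1])
    abort_validation("`magnet_on` must be an increasing interval of length 2")
  structure(list(scopolamine_t = scopolamine_t,
                 pilocarpine1_t = pilocarpine1_t,
                 pilocarpine2_t = pilocarpine2_t,
                 diazepam_t = diazepam_t,
                 magnet_on = as.numeric(magnet_on)),
            class = "ecosyn_timeline")
}

#' @export
print.ecosyn_timeline <- function(x, ...) {
  cat("<ecosyn_timeline> (s): scopolamine", x$scopolamine_t,
      "| pilocarpine", x$pilocarpine1_t, "/", x$pilocarpine2_t,
      "| diazepam", x$diazepam_t,
      "| magnet/sham on [", x$magnet_on[1], ",", x$magnet_on[2], "]\n")
  invisible(x)
}

#' Analysis phase of a time point
#'
#' Maps experiment-clock times onto the three analysis phases:
#' `baseline` before the scopolamine injection, `prediazepam` from the second
#' pilocarpine dose up to (not including) diazepam, and `postdiazepam` from
#' diazepam onward. Times in the induction interval between scopolamine and
#' the second pilocarpine dose belong to none of the phases and map to `NA`.
#'
#' @param t numeric vector of times (s, experiment clock).
#' @param tl an [timeline()] object.
#' @return character vector with values `"baseline"`, `"prediazepam"`,
#'   `"postdiazepam"`, or `NA`.
#' @export
phase_of <- function(t, tl) {
  stopifnot(inherits(tl, "ecosyn_timeline"))
  out <- rep(NA_character_, length(t))
  out[t < tl$scopolamine_t] <- "baseline"
  out[t >= tl$pilocarpine2_t & t < tl$diazepam_t] <- "prediazepam"
  out[t >= tl$diazepam_t] <- "postdiazepam"
  out
}

phase_levels <- c("baseline", "prediazepam", "postdiazepam")
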