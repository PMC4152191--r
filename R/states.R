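#' Default health-state roster
#'
#' Six states: depression status crossed with treatment status, plus the
#' two absorbing states (deceased, retired). The roster is configuration
#' data, not engine structure: further states can be added in a scenario
#' file without any engine change. Flags drive the transition and payoff
#' logic:
#' \describe{
#'   \item{alive}{dead states receive no transitions, costs or utility}
#'   \item{depressed}{remission applies; suicide mortality excess applies;
#'     lost-productive-time cost applies if also employed}
#'   \item{in_treatment}{selects treated vs untreated remission/relapse
#'     rates; gates service-use, antidepressant and turnover costs}
#'   \item{absorbing}{row of the transition matrix is a unit self-loop}
#'   \item{employed}{gates employment-related costs and early retirement}
#' }
#'
#' @return a data.frame with columns `name`, `alive`, `depressed`,
#'   `in_treatment`, `absorbing`, `employed`
#' @export
default_states <- function() {
  data.frame(
    name = c("depressed_treated", "depressed_untreated",
             "recovered_treated", "recovered_untreated",
             "deceased", "retired"),
    alive        = c(TRUE,  TRUE,  TRUE,  TRUE,  FALSE, TRUE),
    depressed    = c(TRUE,  TRUE,  FALSE, FALSE, FALSE, FALSE),
    in_treatment = c(TRUE,  FALSE, TRUE,  FALSE, FALSE, FALSE),
    absorbing    = c(FALSE, FALSE, FALSE, FALSE, TRUE,  TRUE),
    employed     = c(TRUE,  TRUE,  TRUE,  TRUE,  FALSE, FALSE),
    stringsAsFactors = FALSE
  )
}

# name of the first live, non-absorbing state matching the given flags,
# or NA_character_ if the roster has none (the hazard is then dropped)
find_state_name <- function(states, depressed, in_treatment) {
  hit <- states$alive & !states$absorbing &
    states$depressed == depressed & states$in_treatment == in_treatment
  if (!any(hit)) return(NA_character_)
  states$name[which(hit)[1]]
}
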