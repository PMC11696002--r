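#' Simulated-annealing schedule
#'
#' Default values follow the published search configuration: initial
#' temperature 10,000, cooling factor 0.7, reannealing temperature 800,
#' at most 2,500 accepted or 10,000 proposed networks before cooling, at
#' least 500 accepted networks per cooling cycle before reannealing is
#' triggered instead, and up to 10,000 restarts. The wall-clock budget
#' of the original runs is replaced by a deterministic proposal-count
#' budget so that results are reproducible.
#'
#' @param t_initial Initial temperature.
#' @param cooling_factor Multiplicative cooling in (0, 1).
#' @param t_reanneal Reannealing temperature (< t_initial).
#' @param max_accepted_before_cooling,max_proposed_before_cooling
#'   Counter caps that trigger a temperature update.
#' @param min_accepted_before_reanneal Acceptance floor below which the
#'   update reanneals instead of cooling.
#' @param max_restarts Cap on random restarts.
#' @param proposal_budget Total number of proposals per search.
#' @return An object of class `annealing_schedule`.
#' @export
annealing_schedule <- function(t_initial = 10000, cooling_factor = 0.7,
                               t_reanneal = 800,
                               max_accepted_before_cooling = 2500L,
                               max_proposed_before_cooling = 10000L,
                               min_accepted_before_reanneal = 500L,
                               max_restarts = 10000L,
                               proposal_budget = 100000) {
  stopifnot(t_initial > t_reanneal, t_reanneal > 0,
            cooling_factor > 0, cooling_factor < 1,
            proposal_budget > 0)
  structure(list(t_initial = t_initial, cooling_factor = cooling_factor,
                 t_reanneal = t_reanneal,
                 max_accepted_before_cooling =
                   as.integer(max_accepted_before_cooling),
                 max_proposed_before_cooling =
                   as.integer(max_proposed_before_cooling),
                 min_accepted_before_reanneal =
                   as.integer(min_accepted_before_reanneal),
                 max_restarts = as.integer(max_restarts),
                 proposal_budget = proposal_budget),
            class = "annealing_schedule")
}

#' Structure search by simulated annealing
#'
#' Searches DAG space for a high-scoring BDeu structure. Moves add,
#' delete or reverse a random edge, rejecting proposals that would
#' create a cycle or exceed `max_parents`; a score-decreasing move is
#' accepted with probability `exp(delta / T)`. The temperature follows
#' the schedule's cooling/reannealing rules, with random restarts when
#' reannealing stops improving the incumbent. Fully deterministic given
#' the seed.
#'
#' @param data A `discrete_matrix`.
#' @param schedule An [annealing_schedule()].
#' @param max_parents In-degree cap (default 10).
#' @param seed Integer RNG seed.
#' @param ess Equivalent sample size for the BDeu score.
#' @return A list of class `sa_result`: `dag` (best structure found),
#'   `score`, `trace` (incumbent score at each temperature update),
#'   `n_proposed`, `n_accepted`, `n_restarts`.
#' @export
sa_search <- function(data, schedule = annealing_schedule(),
                      max_parents = 10L, seed = 1L, ess = 1) {
  stopifnot(inherits(data, "discrete_matrix"),
            inherits(schedule, "annealing_schedule"))
  if (length(data$genes) < 2L) stop("need at least 2 nodes")
  d <- data_for_cpp(data)
  res <- .cpp_sa_search(d$values, d$levels, ess, as.integer(max_parents),
                        schedule$t_initial, schedule$cooling_factor,
                        schedule$t_reanneal,
                        schedule$max_accepted_before_cooling,
                        schedule$max_proposed_before_cooling,
                        schedule$min_accepted_before_reanneal,
                        schedule$max_restarts, schedule$proposal_budget,
                        as.integer(seed))
  structure(list(dag = dag_from_adjacency(res$adjacency, data$genes),
                 score = res$score, trace = res$trace,
                 n_proposed = res$n_proposed, n_accepted = res$n_accepted,
                 n_restarts = res$n_restarts),
            class = "sa_result")
}

#' Globally optimal structure by exhaustive enumeration
#'
#' Enumerates every DAG over at most five nodes (3 for two nodes, 25 for
#' three, 543 for four, 29281 for five) and returns the maximum-BDeu
#' structure. Serves as the independent optimum against which the
#' annealing search is validated; refuses more than five nodes.
#'
#' @param data A `discrete_matrix` with <= 5 genes.
#' @param ess Equivalent sample size.
#' @return A list with `dag`, `score` and `n_dags` (structures
#'   evaluated).
#' @export
exhaustive_search_oracle <- function(data, ess = 1) {
  stopifnot(inherits(data, "discrete_matrix"))
  if (length(data$genes) > 5L) stop("exhaustive search refuses more than 5 nodes")
  d <- data_for_cpp(data)
  res <- .cpp_exhaustive_search(d$values, d$levels, ess)
  list(dag = dag_from_adjacency(res$adjacency, data$genes),
       score = res$score, n_dags = res$n_dags)
}

#' Repeated searches and consensus construction
#'
#' Runs `n_runs` independent annealing searches (seeds derived
#' deterministically from `seed`) and assembles the edge-frequency
#' consensus network.
#'
#' @param data A `discrete_matrix`.
#' @param n_runs Number of searches (50 in the study design).
#' @param threshold Consensus edge-frequency threshold (inclusive).
#' @param schedule An [annealing_schedule()].
#' @param max_parents In-degree cap.
#' @param seed Master seed.
#' @param ess Equivalent sample size.
#' @return A list with `network` (a `consensus_network`), `dags` and
#'   `scores` of the individual runs.
#' @export
infer_consensus_network <- function(data, n_runs = 50L, threshold = 0.30,
                                    schedule = annealing_schedule(),
                                    max_parents = 10L, seed = 1L, ess = 1) {
  run_seeds <- derive_seeds(seed, n_runs)
  runs <- lapply(seq_len(n_runs), function(i) {
    sa_search(data, schedule = schedule, max_parents = max_parents,
              seed = run_seeds[i], ess = ess)
  })
  dags <- lapply(runs, `[[`, "dag")
  list(network = consensus_network(dags, threshold = threshold),
       dags = dags,
       scores = vapply(runs, `[[`, numeric(1), "score"))
}

# deterministic stream of sub-seeds below 2^31
derive_seeds <- function(seed, n) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  sample.int(.Machine$integer.max, n)
}
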