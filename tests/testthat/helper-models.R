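# Programmatic fixtures: randomized but always-valid flow-limited models.
# Closure constraints are satisfied by construction (body weight and cardiac
# output are derived from the sampled tissues), so these exercise the
# general N-tissue code paths, not just the packaged reference physiology.

random_valid_model <- function(n_tissues = 2L) {
  nm <- paste0("tissue_", letters[seq_len(n_tissues)])
  w <- stats::runif(n_tissues, 0.5, 30)
  q <- stats::runif(n_tissues, 0.2, 3)
  pc <- stats::runif(n_tissues, 0.3, 5)
  er <- c(stats::runif(1, 0.1, 0.9),
          if (n_tissues > 1L) stats::runif(n_tissues - 1L, 0, 0.5))
  blood <- pbpk_blood(volume = stats::runif(1, 2, 6),
                      cardiac_output = sum(q))
  tissues <- Map(pbpk_tissue, nm, w, q, pc, er)
  pbpk_model(blood, unname(tissues),
             initial_amounts = stats::runif(n_tissues + 1L, 0, 5))
}

random_scenario <- function() {
  t0 <- stats::runif(1, 0, 10)
  e0 <- t0 + stats::runif(1, 0, 20)
  e1 <- e0 + stats::runif(1, 10, 100)
  pbpk_scenario(dose = stats::runif(1, 10, 200), t_start = t0,
                t_end = e1 + stats::runif(1, 10, 100),
                expos_start = e0, expos_end = e1)
}

# independent closed-form steady state for constant infusion: blood
# concentration from total extraction, tissues from venous equilibrium
closed_form_steady_state <- function(model, dose) {
  q <- vapply(model$tissues, `[[`, numeric(1), "flow")
  er <- vapply(model$tissues, `[[`, numeric(1), "extraction")
  pc <- vapply(model$tissues, `[[`, numeric(1), "partition")
  c_blood <- dose / sum(q * er)
  c(blood = c_blood, stats::setNames(pc * (1 - er) * c_blood,
                                     names(model$tissues)))
}

complete_metadata <- function() {
  pbpk_metadata(
    model_name = "three-compartment flow-limited demo",
    code_version = "2026-09-28 v1",
    article_citation = "doi:10.0000/example-article",
    code_citation = "doi:10.0000/example-code",
    authors = list(list(name = "A. Modeller", orcid = "0000-0000-0000-0001",
                        contact = "a.modeller@example.org")),
    license = "CC-BY-4.0",
    sources = c("reference adult physiology compendium"),
    ai_tools_disclosure = "none")
}
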