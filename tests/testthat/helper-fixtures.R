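# shared fixtures: the two packaged profiles and the synthetic
# bin-average curve built from the published 2-h tracer-study summary
male <- load_profile("male")
female <- load_profile("female")

jentjens_curve <- function() {
  read_oxidation_curve(
    system.file("extdata", "jentjens_binavg_synthetic.csv",
                package = "fuelbudget"),
    label = "glucose+fructose+sucrose (synthetic bin-average)")
}

# every derived Table-1-style cell for both fixtures at 32% and 20%
expected_budget_cells <- list(
  male = list(demand = 612, remnant = c(`32` = 221, `20` = 138),
              usable = c(`32` = 469, `20` = 552),
              deficit = c(`32` = 143, `20` = 60),
              exogenous = c(`32` = 211, `20` = 128), windfall = 83),
  female = list(demand = 528, remnant = c(`32` = 160, `20` = 100),
                usable = c(`32` = 339, `20` = 399),
                deficit = c(`32` = 189, `20` = 129),
                exogenous = c(`32` = 238, `20` = 178), windfall = 60))
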