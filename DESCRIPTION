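Package: overbookr
Title: Overbooking Policies for Physical Examination Centers with
    Set-Resource Constraints
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools to design and evaluate appointment overbooking policies
    for physical examination centers in which booking limits are set per
    examination set while overage costs accrue per shared resource
    (gastroenteroscope, MRI, and the like). Provides cluster-based
    late-cancellation probability estimation from booking records via staged
    logistic regression, exact (Poisson-binomial) and Monte Carlo show-up
    distributions, expected-net-reward maximization over the feasible
    booking-limit region by complete or greedy search under no-overbooking,
    uniform-probability, and cluster-based policies, discrete-event
    simulation of realized weekly performance, cost-sensitivity analysis,
    and Pareto-frontier reporting of the reward/overage trade-off. Includes
    a synthetic booking-record generator emulating the cluster structure of
    the motivating case study so the full pipeline is testable without
    proprietary data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
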