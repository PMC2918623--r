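Package: aiisim
Title: Closed-Loop Simulation of an Automatic Insulin Infusion System
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: In-silico testbed for a proportional-derivative artificial
    pancreas operating on a subcutaneous continuous glucose sensor. Couples
    a compartmental glucose-insulin model of a type-1 diabetic patient
    (gut absorption, net hepatic glucose balance, insulin-dependent and
    insulin-independent utilization, renal excretion, plasma and active
    insulin pools) to a first-order lagged amperometric sensor model with
    Gaussian noise and 5-minute averaging, a tanh proportional-derivative
    insulin controller with an emergency dextrose rescue, and quantized
    clinical infusion pumps. Provides scenario builders for meal, oral
    glucose, and intravenous glucose/insulin challenges, a fast compiled
    closed-loop integrator, stability metrics (overshoot, undershoot,
    settling time), and parameter-sweep tables across body weight and
    hepatic insulin sensitivity.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
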