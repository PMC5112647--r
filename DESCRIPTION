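Package: orsim
Title: Discrete Event Simulation of Operating-Room Days Under Alternative
    Neuromuscular Block Reversal Strategies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A discrete event simulation of a single operating room over a
    working month, built to compare neuromuscular block reversal strategies
    (sugammadex versus neostigmine) on operating-room efficiency and on
    residual neuromuscular blockade and its respiratory complications.
    Models the OR day as a sequence of stochastic activities (first-patient
    delay, procedures, turnovers, emergency insertions, cleanup) under
    hospital policies for time-over-run cancellation and paid staff
    overtime, and couples the two reversal arms with common random numbers
    so that between-arm differences isolate the intervention effect.
    Includes scenario sweeps over the proportion of patients verified to
    full neuromuscular recovery before extubation, policy sensitivity
    analyses, and a deep-block exploratory analysis, with number-needed-to-
    treat summaries for avoided residual blockade, hypoxemia and upper
    airway obstruction.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    optparse,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
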