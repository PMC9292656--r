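Package: donorflow
Title: Discrete-Event Simulation of a Whole-Blood Collection Centre
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: An event-driven simulation of donor flow through a fixed-site
    whole-blood collection centre: registration, haemoglobin screening,
    medical consultation, phlebotomy, rest and refreshment, with booked and
    walk-in donors competing for clerks, physicians, nurses and beds. The
    package generates period-structured appointment schedules, runs
    factorial experiments over centre layouts under common random numbers,
    computes cycle-time, queue-time, utilisation and cost indicators,
    analyses them by ANOVA and cost-efficiency regression, and feeds
    re-calibrated scheduling parameters back into a revised day plan.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    yaml,
    jsonlite
Suggests: testthat (>= 3.0.0), optparse, withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
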