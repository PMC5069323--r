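Package: mcisim
Title: Discrete-Event Simulation of Pre-Hospital Mass Casualty Incident Response
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A victim-centred discrete-event simulator for the pre-hospital
    phase of a mass casualty incident (MCI). Victims carry clinical-condition
    state machines scored with the RPM injury severity score (coded
    respiratory rate, pulse rate and best motor response) and deteriorate
    over time on a tabulated survival grid unless treated by responders of
    increasing skill (EMT, PIT, MMT). The medical response model moves
    victims from the incident site through a casualty collection point,
    forward medical post and non-urgent care area to hospitals under
    configurable operational policies (scoop-and-run versus stay-and-play,
    triage on or off, search-and-rescue rates, resource and supervision
    levels, hospital distribution rules and surge capacities). A
    full-factorial experiment harness with replication management and
    one-way ANOVA / Scheffe reporting measures mortality effects across the
    seven interventional factors.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite,
    knitr,
    rmarkdown
Config/testthat/edition: 3
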