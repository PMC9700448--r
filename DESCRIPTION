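Package: admitflow
Title: Discrete-Event Simulation of Emergency-Department Admission Flow
Version: 0.1.0
Authors@R:
    person("admitflow", "maintainers", email = "admitflow@example.org",
           role = c("aut", "cre"))
Description: Discrete-event simulation of the patient pathway from
    emergency-department (ED) arrival to delivery into an assigned
    inpatient bed.  The pathway is modelled as seven sequential
    multi-server stations (registration, triage, assessment, referral to
    medicine, decision to admit, room allocation, physical transfer) with
    triangular duration distributions fitted by moment matching, three
    inpatient bed pools, and a scenario engine for staffing and
    bed-capacity interventions.  Includes a replication protocol with
    warm-up handling, Welch t-test validation against a synthetic
    patient-level reference dataset, scenario ranking with common random
    numbers, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    optparse,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
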