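# Resuscitation-success ceiling `a` (the asymptotic fraction of patients
# achieving return of spontaneous circulation under continued CPR) as a
# function of the initial burial time of the extricated pulseless patient.
# The ceiling drops with burial time because longer hypoxia precedes the
# arrest; at 35 min and beyond the chance of ROSC is taken as zero.
version: "1.0"
entries:
  - {t_burial_min: 12, a: 0.62}
  - {t_burial_min: 20, a: 0.25}
  - {t_burial_min: 35, a: 0.00}
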