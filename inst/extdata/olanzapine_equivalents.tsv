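drug	factor_mg_olz_per_mg
olanzapine	1.0
chlorpromazine	0.0333
haloperidol	2.0
fluphenazine	2.0
perphenazine	0.667
sulpiride	0.025
amisulpride	0.0286
risperidone	3.333
paliperidone	2.222
quetiapine	0.0267
clozapine	0.05
aripiprazole	0.667
ziprasidone	0.125
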