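new england journal of medicine
lancet
jama
bmj
annals of internal medicine
nature medicine
plos one
journal of clinical oncology
circulation research
american journal of cardiology
journal of the american college of cardiology
pediatrics research
journal of clinical investigation
american journal of epidemiology
journal of infectious diseases
clinical infectious diseases
diabetes care
archives of internal medicine
journal of biological chemistry
proceedings of the national academy of sciences
bioinformatics journal
nucleic acids research
journal of medical internet research
academic medicine
journal of general internal medicine
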