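hypertension
diabetes mellitus
asthma
myocardial infarction
neoplasms
breast neoplasms
lung neoplasms
stroke
obesity
depression
anxiety disorders
alzheimer disease
parkinson disease
epilepsy
migraine disorders
osteoporosis
arthritis
rheumatoid arthritis
osteoarthritis
tuberculosis
malaria
influenza
pneumonia
hepatitis
hepatitis c
hiv infections
sepsis
anemia
leukemia
lymphoma
melanoma
psoriasis
eczema
dermatitis
glaucoma
cataract
schizophrenia
bipolar disorder
autism spectrum disorder
attention deficit disorder
insomnia
sleep apnea
chronic kidney disease
renal insufficiency
heart failure
atrial fibrillation
coronary artery disease
atherosclerosis
hyperlipidemia
hypercholesterolemia
hypothyroidism
hyperthyroidism
pregnancy
preeclampsia
preterm birth
cystic fibrosis
sickle cell anemia
hemophilia
thrombosis
pulmonary embolism
copd
emphysema
bronchitis
gastritis
peptic ulcer
crohn disease
ulcerative colitis
irritable bowel syndrome
celiac disease
pancreatitis
cirrhosis
gallstones
appendicitis
meningitis
encephalitis
multiple sclerosis
muscular dystrophy
fibromyalgia
lupus erythematosus
scleroderma
vasculitis
endometriosis
infertility
menopause
prostatic neoplasms
colorectal neoplasms
ovarian neoplasms
cervical neoplasms
pancreatic neoplasms
gastric neoplasms
thyroid neoplasms
bladder neoplasms
kidney neoplasms
brain neoplasms
bone neoplasms
liver neoplasms
esophageal neoplasms
dementia
delirium
aphasia
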