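high blood pressure
sugar
heart attack
cancer treatment
weight loss
back pain
headache remedies
flu symptoms
cold medicine
sore throat
skin rash
allergy
vitamin deficiency
cholesterol diet
exercise benefits
smoking cessation
alcohol effects
stress management
memory loss
joint pain
knee injury
broken bone
burn treatment
wound healing
antibiotics side effects
vaccine safety
child fever
baby sleep
pregnancy diet
birth control
menstrual cramps
hair loss
acne treatment
sunburn
dehydration
food poisoning
stomach ache
constipation
diarrhea remedies
heartburn
acid reflux
kidney stones
urinary infection
prostate health
breast lump
mole changes
fatigue causes
dizziness
fainting
numbness
tingling hands
swollen ankles
shortness of breath
chest tightness
palpitations
snoring
night sweats
hot flashes
mood swings
panic attacks
social anxiety
eating disorder
bulimia
anorexia
caffeine effects
herbal supplements
fish oil
probiotics
gluten sensitivity
lactose intolerance
blood thinner
pain relievers
ibuprofen dosage
acetaminophen overdose
antidepressants
sleeping pills
blood donation
organ transplant
physical therapy
chemotherapy side effects
radiation therapy
surgery recovery
anesthesia risks
hospital infection
telemedicine
genetic testing
stem cells
clinical trial
placebo effect
immune system
inflammation diet
antioxidants
blood sugar monitor
insulin pump
glucose levels
healthy aging
longevity
meditation benefits
yoga health
hydration
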