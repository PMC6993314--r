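# Bundled lexicons for the synthetic generator and the surrogate samplers.
# All name/place material is public-domain common-usage wordlist content;
# no real patient data appears anywhere in the package.

lex_first_names <- c(
  "James", "Mary", "Robert", "Patricia", "Michael", "Linda", "David",
  "Barbara", "William", "Susan", "Richard", "Jessica", "Joseph", "Sarah",
  "Thomas", "Karen", "Charles", "Nancy", "Daniel", "Lisa", "Matthew",
  "Betty", "Anthony", "Helen", "Mark", "Sandra", "Paul", "Donna", "Steven",
  "Carol", "Andrew", "Ruth", "Kenneth", "Sharon", "George", "Michelle",
  "Joshua", "Laura", "Kevin", "Emily", "Brian", "Kimberly", "Edward",
  "Deborah", "Ronald", "Dorothy", "Timothy", "Amy", "Jason", "Angela")

lex_last_names <- c(
  "Smith", "Johnson", "Williams", "Brown", "Jones", "Garcia", "Miller",
  "Davis", "Rodriguez", "Martinez", "Hernandez", "Lopez", "Gonzalez",
  "Wilson", "Anderson", "Thomas", "Taylor", "Moore", "Jackson", "Martin",
  "Lee", "Perez", "Thompson", "White", "Harris", "Sanchez", "Clark",
  "Ramirez", "Lewis", "Robinson", "Walker", "Hall", "Allen", "Torres",
  "Nguyen", "Wright", "Flores", "Scott", "Rivera", "Morales", "Cooper",
  "Peterson", "Bailey", "Reed", "Kelly", "Howard", "Ramos", "Cox",
  "Diaz", "Bennett")

# dictionary-word surnames used by the generator's difficulty knob: these
# collide with ordinary English words and are the classic hard false-negative
lex_dictionary_names <- c("Guy", "Strong", "Young", "Stone", "Price",
                          "Hope", "Grace", "Rich")

lex_cities <- c(
  "Springfield", "Riverside", "Franklin", "Greenville", "Bristol",
  "Clinton", "Fairview", "Salem", "Madison", "Georgetown", "Arlington",
  "Ashland", "Dover", "Hudson", "Kingston", "Milton", "Newport", "Oxford",
  "Burlington", "Lexington", "Concord", "Dayton", "Florence", "Jackson",
  "Lancaster", "Manchester", "Marion", "Quincy", "Trenton", "Winchester")

lex_hospital_suffixes <- c("General Hospital", "Medical Center",
                           "Community Hospital", "Memorial Hospital")

lex_months <- c("January", "February", "March", "April", "May", "June",
                "July", "August", "September", "October", "November",
                "December")

lex_professions <- c("teacher", "carpenter", "electrician", "accountant",
                     "librarian", "plumber", "farmer", "chef", "architect",
                     "journalist", "pharmacist", "musician", "firefighter",
                     "pilot", "barber")

# location jargon: unit abbreviations used as LOCATION PHI in nursing-style
# notes; the two sets are disjoint so a domain pair can hold jargon out of
# the source corpus entirely
lex_jargon_a <- c("CCU", "NICU", "TSICU", "PACU")
lex_jargon_b <- c("MICU", "PMICU", "SICU", "SDU")

# shared clinical filler sentences (no PHI); a few deliberately reuse the
# "now in"/"transferred" phrasing with non-PHI continuations so location
# cues are not trivially separable
lex_filler_shared <- c(
  "Patient remains stable on current regimen.",
  "Vital signs within normal limits overnight.",
  "Continue current medications and monitor closely.",
  "No acute distress noted on examination.",
  "Labs reviewed and discussed with the team.",
  "Patient tolerated the procedure well.",
  "Plan to reassess in the morning.",
  "Now in stable condition after treatment.",
  "Patient now in recovery and resting comfortably.",
  "Transferred care to the covering team.",
  "Diet advanced as tolerated.",
  "Pain controlled with current regimen.",
  "Family updated at the bedside.",
  "Will follow up pending results.",
  "Oxygen saturation acceptable on room air.",
  # non-PHI clinical abbreviations: uppercase distractors that compete with
  # unit jargon and record numbers at aggressive decoding biases
  "HR 82 with BP 118/76 recorded.",
  "CXR reviewed with no acute findings.",
  "ABG pending this afternoon.",
  "O2 weaned to 2 L nasal cannula.",
  "EKG unchanged from prior tracing.",
  "CBC and BMP within normal limits.")

# non-PHI clinical abbreviations used in generated status sentences
lex_abbrevs <- c("NPO", "TELE", "PRN", "BID", "PT", "OT", "IV", "NS",
                 "UA", "LFT", "INR", "TSH", "MRI", "CT", "EEG", "DNR")

# domain-specific filler vocabulary: two disjoint sets of clinical terms so
# a vocabulary shift between corpora can be dialed in
lex_domain_words_a <- c(
  "metoprolol", "lisinopril", "troponin", "angiogram", "stent",
  "echocardiogram", "afib", "cardiology", "telemetry", "diuresis",
  "furosemide", "ejection", "systolic", "perfusion", "ischemia")

lex_domain_words_b <- c(
  "vancomycin", "ventilator", "sedation", "propofol", "extubation",
  "tracheostomy", "pressors", "norepinephrine", "sepsis", "lactate",
  "intubated", "weaning", "secretions", "suctioning", "fentanyl")

# varied cue verbs for name sentences; variety forces generalization across
# cues rather than memorization of a single pattern
lex_name_cues <- c("seen", "examined", "evaluated", "assessed",
                   "interviewed", "reviewed", "visited", "consulted")

# a small general-English vocabulary for coverage-controlled baseline
# embeddings (deliberately free of clinical cue words)
lex_general_words <- c(
  "the", "and", "was", "for", "with", "this", "that", "from", "have",
  "been", "were", "are", "not", "but", "his", "her", "they", "will",
  "would", "there", "when", "which", "about", "after", "before", "over",
  "under", "again", "more", "most", "other", "some", "such", "only",
  "than", "then", "these", "also", "into", "through")
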