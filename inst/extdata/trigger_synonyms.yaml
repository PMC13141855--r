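# Trigger synonym dictionary: raw curation label -> taxonomy entry.
# Categories: kinesigenic, exercise_induced, non_kinesigenic.
# Subtypes apply to non_kinesigenic triggers only.
# Lookup is case-insensitive; edit or extend freely and pass the file to
# map_trigger(dictionary = ...).
kinesigenic: {category: kinesigenic}
sudden movement: {category: kinesigenic}
movement initiation: {category: kinesigenic}
movement: {category: kinesigenic}
abrupt movement: {category: kinesigenic}
standing up: {category: kinesigenic}
postural change: {category: kinesigenic}
exercise: {category: exercise_induced}
exertion: {category: exercise_induced}
physical activity: {category: exercise_induced}
sports: {category: exercise_induced}
alcohol: {category: non_kinesigenic, subtype: alcohol}
ethanol: {category: non_kinesigenic, subtype: alcohol}
tobacco: {category: non_kinesigenic, subtype: tobacco}
smoking: {category: non_kinesigenic, subtype: tobacco}
nicotine: {category: non_kinesigenic, subtype: tobacco}
sleep deprivation: {category: non_kinesigenic, subtype: sleep_deprivation}
lack of sleep: {category: non_kinesigenic, subtype: sleep_deprivation}
tiredness after poor sleep: {category: non_kinesigenic, subtype: sleep_deprivation}
physiological stress: {category: non_kinesigenic, subtype: physiological_stress}
fever: {category: non_kinesigenic, subtype: physiological_stress}
illness: {category: non_kinesigenic, subtype: physiological_stress}
infection: {category: non_kinesigenic, subtype: physiological_stress}
intercurrent illness: {category: non_kinesigenic, subtype: physiological_stress}
fatigue: {category: non_kinesigenic, subtype: fatigue}
exhaustion: {category: non_kinesigenic, subtype: fatigue}
fasting: {category: non_kinesigenic, subtype: fasting}
hunger: {category: non_kinesigenic, subtype: fasting}
missed meal: {category: non_kinesigenic, subtype: fasting}
caffeine: {category: non_kinesigenic, subtype: caffeine}
coffee: {category: non_kinesigenic, subtype: caffeine}
startle: {category: non_kinesigenic, subtype: startle}
sudden noise: {category: non_kinesigenic, subtype: startle}
fright: {category: non_kinesigenic, subtype: startle}
heat: {category: non_kinesigenic, subtype: heat}
hot weather: {category: non_kinesigenic, subtype: heat}
hot bath: {category: non_kinesigenic, subtype: heat}
anxiety: {category: non_kinesigenic, subtype: anxiety}
nervousness: {category: non_kinesigenic, subtype: anxiety}
menstruation: {category: non_kinesigenic, subtype: menstruation}
menses: {category: non_kinesigenic, subtype: menstruation}
excitement: {category: non_kinesigenic, subtype: excitement}
emotional stress: {category: non_kinesigenic, subtype: emotional_stress}
stress: {category: non_kinesigenic, subtype: emotional_stress}
emotion: {category: non_kinesigenic, subtype: emotional_stress}
other: {category: non_kinesigenic, subtype: other}
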