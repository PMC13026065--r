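indicator,direction,dimension,ref_weight
mild_activity,positive,health exercise,1.43
moderate_activity,positive,health exercise,4.33
vigorous_activity,positive,health exercise,0.48
smoking,negative,health habits,1.39
drinking,negative,health habits,2.59
night_sleep_duration,positive,health habits,0.44
afternoon_nap,positive,health habits,0.63
interacted_with_friends,positive,health social interaction,2.28
interacted_with_friends_freq,positive,health social interaction,2.49
games_or_club,positive,health social interaction,3.73
games_or_club_freq,positive,health social interaction,3.93
helped_others,positive,health social interaction,4.80
helped_others_freq,positive,health social interaction,4.98
sport_or_social_club,positive,health social interaction,5.78
sport_or_social_club_freq,positive,health social interaction,5.90
community_organization,positive,health social interaction,8.43
community_organization_freq,positive,health social interaction,8.55
voluntary_work,positive,health social interaction,7.67
voluntary_work_freq,positive,health social interaction,7.77
education_course,positive,health social interaction,11.36
education_course_freq,positive,health social interaction,11.04
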